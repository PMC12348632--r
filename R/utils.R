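# internal helpers

# round half away from zero (commercial rounding); base round() is banker's
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a string; used only to stamp provenance lines.
# 32-bit arithmetic emulated in doubles (split multiply keeps products < 2^53).
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), b) + (h %/% 2147483648) * 2147483648
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# simple pipe-free markdown table renderer for report.md
md_table <- function(df, align = NULL) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, format = "g", digits = 6) else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

stop_bwsqol <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "bwsqol_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
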