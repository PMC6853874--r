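# Shared fixtures: a standard autofluorescence model, a synthetic FCS 3.x
# writer (binary fixtures are generated at test time, never shipped), and a
# numeric-integration oracle for convolution tail probabilities.

std_noise <- function(mean = 100, variance = 225) {
  noise_model("gamma", mean = mean, variance = variance)
}

# Minimal FCS 3.1 writer used only to exercise read_fcs(); list-mode data,
# float (F) or double (D), either byte order.
write_fcs_synthetic <- function(path, mat, datatype = "F",
                                byteord = "1,2,3,4") {
  npar <- ncol(mat); ntot <- nrow(mat)
  size <- if (datatype == "F") 4L else 8L
  kw <- c("$DATATYPE", datatype, "$MODE", "L", "$BYTEORD", byteord,
          "$PAR", npar, "$TOT", ntot)
  for (i in seq_len(npar)) {
    kw <- c(kw, sprintf("$P%dN", i), colnames(mat)[i],
            sprintf("$P%dB", i), size * 8L)
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  tb <- 58L; te <- tb + nchar(text) - 1L; db <- te + 1L
  de <- db + npar * ntot * size - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", tb, te, db, de, 0L, 0L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(mat)), con, size = size,
           endian = if (startsWith(byteord, "1")) "little" else "big")
  invisible(path)
}

# P(S + N > t) for S ~ Gamma(k, theta) and independent Gamma noise, by
# numeric integration -- the oracle for percent_outliers on synthetic data.
convolved_tail_prob <- function(t, shape, scale, noise_mean, noise_var) {
  ns <- noise_mean^2 / noise_var
  nt <- noise_var / noise_mean
  f <- function(s) {
    dgamma(s, shape = shape, scale = scale) *
      pgamma(t - s, shape = ns, scale = nt, lower.tail = FALSE)
  }
  stats::integrate(f, 0, t, rel.tol = 1e-9)$value +
    pgamma(t, shape = shape, scale = scale, lower.tail = FALSE)
}
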