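# Discrete wavelet transform with periodized boundaries, and soft-threshold
# denoising. No wavelet package ships with the R stack used here, so the
# pyramid algorithm is implemented directly; filter banks are the standard
# Daubechies coefficients.

# Daubechies orthonormal low-pass decomposition filters (db4 = 8 taps,
# db6 = 12 taps). High-pass and reconstruction filters follow from the
# quadrature-mirror relations.
db_filters <- list(
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db6 = c(-0.0010773010853084796, 0.004777257510945511,
          0.0005538422011614961, -0.03158203931748603,
          0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983,
          0.31525035170919763, 0.7511339080210954,
          0.49462389039845306, 0.11154074335010947))

wavelet_bank <- function(family) {
  lo <- db_filters[[family]]
  if (is.null(lo)) stopf("unknown wavelet family '%s'", family)
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)   # QMF: g[k] = (-1)^k h[L-1-k]
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = L)
}

# One level of the periodized DWT. x must have even length.
dwt_step <- function(x, bank) {
  n <- length(x)
  L <- bank$length
  # pywt-compatible 'periodization': extend circularly so that output k
  # uses x[(2k + j - L/2) mod n] style alignment; implement by circular
  # convolution then decimation.
  reps <- ceiling((L - 1) / n)
  xp <- c(rep(x, reps), x, x[seq_len(L)])        # x periodically extended
  off <- reps * n
  conv <- function(filt) {
    out <- numeric(n %/% 2L)
    for (k in seq_len(n %/% 2L)) {
      i0 <- off + 2L * k - 1L                    # aligned start
      seg <- xp[(i0 - L + 2L):(i0 + 1L)]
      out[k] <- sum(rev(filt) * seg)
    }
    out
  }
  list(approx = conv(bank$dec_lo), detail = conv(bank$dec_hi))
}

idwt_step <- function(approx, detail, bank) {
  n2 <- length(approx)
  n <- 2L * n2
  L <- bank$length
  up <- function(v) { out <- numeric(n); out[seq(1, n, 2)] <- v; out }
  ua <- up(approx)
  ud <- up(detail)
  out <- numeric(n)
  # transpose of the analysis operator: circular correlation
  for (j in seq_len(L)) {
    shift <- j - 2L
    idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
    out <- out + bank$rec_lo[L - j + 1L] * ua[idx] +
      bank$rec_hi[L - j + 1L] * ud[idx]
  }
  out
}

# Full periodized multilevel DWT; odd lengths are padded by repeating the
# last sample (padding recorded for exact-length reconstruction).
dwt_periodic <- function(x, family = "db6", level = 3L) {
  bank <- wavelet_bank(family)
  details <- vector("list", level)
  pads <- integer(level)
  cur <- x
  for (l in seq_len(level)) {
    if (length(cur) < 2L)
      stopf("signal of length %d is too short for a level-%d transform",
            length(x), level)
    if (length(cur) %% 2L == 1L) {
      cur <- c(cur, cur[length(cur)])
      pads[l] <- 1L
    }
    st <- dwt_step(cur, bank)
    details[[l]] <- st$detail
    cur <- st$approx
  }
  list(approx = cur, details = details, pads = pads, family = family,
       level = level, n = length(x))
}

idwt_periodic <- function(decomp) {
  bank <- wavelet_bank(decomp$family)
  cur <- decomp$approx
  for (l in rev(seq_len(decomp$level))) {
    cur <- idwt_step(cur, decomp$details[[l]], bank)
    if (decomp$pads[l] == 1L) cur <- cur[-length(cur)]
  }
  cur
}

#' Wavelet soft-threshold denoising of a spectrum
#'
#' Decomposes the spectrum to `level` scales with a periodized Daubechies
#' transform, soft-thresholds all detail coefficients at the universal
#' threshold \eqn{\sigma \sqrt{2 \log n}} (with \eqn{\sigma} estimated from
#' the median absolute deviation of the finest-scale details), and
#' reconstructs. Output length equals input length.
#'
#' @param spectrum numeric vector.
#' @param family `"db6"` (default, the 12-tap Daubechies filter) or
#'   `"db4"`.
#' @param level decomposition depth.
#' @param threshold soft-threshold value; `NULL` (default) uses the
#'   universal threshold.
#' @return the denoised spectrum, same length as the input.
#' @export
wavelet_denoise <- function(spectrum, family = "db6", level = 3L,
                            threshold = NULL) {
  spectrum <- as.numeric(spectrum)
  level <- check_count(level, "level")
  minlen <- 2L^level
  if (length(spectrum) < minlen)
    stopf("need at least %d samples for a level-%d transform", minlen, level)
  dec <- dwt_periodic(spectrum, family = family, level = level)
  if (is.null(threshold)) {
    fine <- dec$details[[1L]]
    sigma <- stats::median(abs(fine - stats::median(fine))) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(spectrum)))
  }
  soft <- function(w) sign(w) * pmax(abs(w) - threshold, 0)
  dec$details <- lapply(dec$details, soft)
  idwt_periodic(dec)
}

#' Denoise every spectrum of a table
#'
#' Applies [wavelet_denoise()] row-wise (i.e. pixel-wise when rows are ROI
#' pixels), keeping labels and provenance.
#'
#' @param table a [spectra_table()].
#' @inheritParams wavelet_denoise
#' @return the denoised [spectra_table()].
#' @export
denoise_spectra <- function(table, family = "db6", level = 3L,
                            threshold = NULL) {
  stopifnot(inherits(table, "spectra_table"))
  Xd <- t(apply(table$X, 1L, wavelet_denoise, family = family,
                level = level, threshold = threshold))
  spectra_table(Xd, table$wavelengths, labels = table$labels,
                provenance = table$provenance)
}
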