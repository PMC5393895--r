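# External patterns, the memorization/recall protocol, and network readouts.
#
# An external pattern (EP) is a binary mask over the e-population driven by a
# constant current during a time window.  Memorization runs the network with
# the EP and plasticity enabled; recall re-runs it with plasticity switched
# off and the memorized weights frozen.  Readouts: population-mean firing
# rate F, pairwise spike-train coherence, and the recall quality C comparing
# the memorization-phase and recall-phase spike patterns.

#' Spike raster container
#'
#' @param cell integer cell ids.
#' @param t spike times (ms).
#' @param N population size.
#' @param T_total record duration (ms).
#' @return A `glia_raster` data frame (`cell`, `t`) with attributes `N` and
#'   `T_total`.
#' @export
spike_raster <- function(cell, t, N, T_total) {
  stopifnot(length(cell) == length(t), N >= 0, T_total >= 0)
  tol <- 1e-6 * max(1, T_total)  # accumulated-dt rounding at the last step
  if (length(t) && (min(t) < 0 || max(t) > T_total + tol))
    stop("spike times outside [0, T]", call. = FALSE)
  if (length(cell) && (min(cell) < 1 || max(cell) > N))
    stop("cell ids outside the population", call. = FALSE)
  out <- data.frame(cell = as.integer(cell), t = as.numeric(t))
  attr(out, "N") <- as.integer(N)
  attr(out, "T_total") <- as.numeric(T_total)
  class(out) <- c("glia_raster", "data.frame")
  out
}

#' External pattern from a binary mask
#'
#' @param mask logical/0-1 vector over the e-population (length `n_e`).
#' @param amplitude injected current (uA/cm^2, >= 0).
#' @param onset,offset injection window (ms), `onset < offset`.
#' @param id optional pattern label.
#' @return A `glia_ep` object.
#' @export
ep_from_matrix <- function(mask, amplitude = 10, onset = 0, offset = Inf,
                           id = "EP") {
  stopifnot(amplitude >= 0, onset < offset)
  structure(list(mask = as.logical(mask), amplitude = amplitude,
                 onset = onset, offset = offset, id = id),
            class = "glia_ep")
}

read_pbm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1L] != "P1") stop("not a plain PBM (P1) file: ", path, call. = FALSE)
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  bits <- as.integer(strsplit(paste(tok[-(1:3)], collapse = ""), "")[[1L]])
  if (length(bits) != w * h) stop("corrupt PBM raster: ", path, call. = FALSE)
  matrix(bits, nrow = h, ncol = w, byrow = TRUE)  # 1 = black
}

#' External pattern from a bitmap image
#'
#' Reads a PNG or plain PBM (P1) image; dark pixels become driven cells.
#' Pixels are mapped row-major onto cell indices with nearest-pixel
#' resampling when the pixel count differs from `n_e`.
#'
#' @param path image file (`.png` or `.pbm`), or an already-loaded 0/1
#'   matrix (1 = on).
#' @param n_e e-population size.
#' @inheritParams ep_from_matrix
#' @return A `glia_ep` object.
#' @export
ep_from_image <- function(path, n_e, amplitude = 10, onset = 0, offset = Inf,
                          id = "EP") {
  img <- if (is.matrix(path)) path
  else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    lum <- if (length(dim(a)) == 3L)
      0.2126 * a[, , 1L] + 0.7152 * a[, , 2L] + 0.0722 * a[, , 3L]
    else a
    (lum < 0.5) * 1L   # dark = on
  } else if (grepl("\\.pbm$", path, ignore.case = TRUE)) {
    read_pbm(path)
  } else stop("unreadable pattern image (expect .png or .pbm): ", path,
              call. = FALSE)
  if (!length(img)) stop("empty bitmap", call. = FALSE)
  flat <- as.integer(t(img))  # row-major
  m <- length(flat)
  pix <- floor((seq_len(n_e) - 1) * m / n_e) + 1L
  ep_from_matrix(flat[pix] > 0, amplitude, onset, offset, id)
}

#' Population-mean firing rate F
#'
#' `F = (1/N) sum_i f_i` in Hz, where `f_i` is cell i's spike count divided
#' by the record duration; silent cells contribute zero.
#'
#' @param raster a `glia_raster`.
#' @return scalar, Hz.
#' @export
mean_frequency <- function(raster) {
  N <- attr(raster, "N"); T_total <- attr(raster, "T_total")
  if (is.null(T_total) || T_total <= 0)
    stop("mean_frequency needs a positive record duration", call. = FALSE)
  if (N == 0) return(0)
  mean(tabulate(raster$cell, nbins = N)) * 1000 / T_total
}

#' Pairwise spike-train coherence
#'
#' Spike trains are binarized into bins of width `bin`; for each cell pair
#' `kappa_ij = sum_l X_i(l) X_j(l) / sqrt(sum_l X_i(l) * sum_l X_j(l))`, and
#' the statistic is the mean over all pairs of active cells.  Cells with no
#' spikes are excluded; with fewer than two active cells the metric is
#' undefined and `NA` is returned (with a warning), which is distinct from a
#' coherence of zero.
#'
#' @param raster a `glia_raster`.
#' @param bin bin width (ms, > 0).
#' @return scalar in `[0, 1]`, or `NA` if undefined.
#' @export
synchronization <- function(raster, bin = 2) {
  stopifnot(bin > 0)
  T_total <- attr(raster, "T_total")
  active <- sort(unique(raster$cell))
  if (length(active) < 2L) {
    warning("synchronization undefined: fewer than 2 active cells")
    return(NA_real_)
  }
  L <- max(1L, ceiling(T_total / bin))
  bins <- pmin(pmax(ceiling(raster$t / bin), 1L), L)
  X <- matrix(0L, length(active), L)
  X[cbind(match(raster$cell, active), bins)] <- 1L
  cross <- tcrossprod(X)
  counts <- rowSums(X)
  kap <- cross / sqrt(outer(counts, counts))
  mean(kap[upper.tri(kap)])
}

#' Recall quality C
#'
#' Cosine similarity between the per-neuron spike-count vectors of a
#' reference raster and a test raster over windows of equal length.  Two
#' silent windows are identical, so C is defined as 1; one silent window
#' against an active one gives 0.
#'
#' @param ref,test `glia_raster` objects over the same population.
#' @param window length-2 numeric, the time window (applied to both rasters);
#'   default is each raster's full record.
#' @param test_window optional separate window for `test` (same length as
#'   `window`).
#' @return A `glia_recall` list: `C`, the two windows, and the per-neuron
#'   count vectors used.
#' @export
recall_quality <- function(ref, test, window = NULL, test_window = NULL) {
  N <- attr(ref, "N")
  if (!identical(N, attr(test, "N")))
    stop("recall_quality: population sizes differ", call. = FALSE)
  if (is.null(window)) window <- c(0, attr(ref, "T_total"))
  if (is.null(test_window)) test_window <- window
  if (abs(diff(window) - diff(test_window)) > 1e-9)
    stop("recall_quality: windows must have equal length", call. = FALSE)
  counts_in <- function(r, w) {
    sel <- r$t >= w[1L] & r$t <= w[2L]
    tabulate(r$cell[sel], nbins = N)
  }
  a <- counts_in(ref, window); b <- counts_in(test, test_window)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  C <- if (na == 0 && nb == 0) 1 else if (na == 0 || nb == 0) 0 else
    sum(a * b) / (na * nb)
  structure(list(C = C, ref_window = window, test_window = test_window,
                 ref_counts = a, test_counts = b),
            class = "glia_recall")
}

#' Run a memorization stage
#'
#' Simulates the configured network with the external pattern injected and
#' the plasticity rule active; the result carries the spike rasters and the
#' final (memorized) weight matrix.
#'
#' @param config a `glia_config`.
#' @param ep a `glia_ep`.
#' @param rule an enabled [plasticity_rule()].
#' @param ... passed to [simulate_network()].
#' @return A `glia_result`.
#' @export
run_memorization <- function(config, ep, rule, ...) {
  if (!rule$enabled) stop("memorization requires an enabled plasticity rule",
                          call. = FALSE)
  config$plasticity <- rule
  simulate_network(config, ep = ep, ...)
}

#' Run a recall stage
#'
#' Re-simulates with plasticity switched off and the weight matrix frozen at
#' its memorized values; the returned connectivity is bitwise identical to
#' the input weights.
#'
#' @param config a `glia_config`.
#' @param memorized a `glia_connectivity` (e.g. `result$connectivity` from
#'   [run_memorization()]).
#' @param ep a `glia_ep`.
#' @param ... passed to [simulate_network()].
#' @return A `glia_result`.
#' @export
run_recall <- function(config, memorized, ep, ...) {
  config$plasticity <- plasticity_rule("NONE")
  simulate_network(config, ep = ep, connectivity = memorized, ...)
}
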