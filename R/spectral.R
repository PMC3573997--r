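# Period-range bins in seconds, longest period first. Each row is
# (period_hi_s, period_lo_s), both ends inclusive.
.binset_tables <- list(
  DANIO_XENOPUS_18 = matrix(c(
    598, 298,   200, 149,   120, 99,    85, 54,    49, 33,
    29, 20.5,   21, 17,     16, 15,     14, 13,    12, 11,
    10, 5,      4.9, 3.5,   3.3, 2.5,   2.4, 1.7,  1.6, 1,
    0.9, 0.33,  0.3, 0.25,  0.24, 0.1), ncol = 2, byrow = TRUE),
  RADIX_STAGE_18 = matrix(c(
    598, 299,   291, 145,   120, 100,   85, 75,    66, 60,
    54, 50,     46, 43,     40, 37,     35, 30,    29, 24,
    20, 17,     15, 12.5,   12.2, 10,   9.5, 5,    2, 1.1,
    1, 0.68,    0.66, 0.5,  0.3, 0.26), ncol = 2, byrow = TRUE),
  RADIX_STRESSOR_30 = matrix(c(
    300, 150,   100, 75,    60, 50,     43, 37.5,  33.5, 30,
    27.5, 25,   23, 21.5,   20, 19,     17.5, 16.5, 16, 14.5,
    13.5, 12.5, 12, 11,     10.5, 9.5,  9, 6.5,    6.3, 5,
    4.9, 3.5,   3.3, 2.5,   2.4, 2,     1.9, 1.5,  1.4, 1,
    0.9, 0.8,   0.7, 0.65,  0.6, 0.5,   0.49, 0.4, 0.39, 0.34,
    0.33, 0.28, 0.27, 0.22, 0.21, 0.18, 0.17, 0.15, 0.14, 0.13),
    ncol = 2, byrow = TRUE)
)

#' Frequency bin sets
#'
#' A `frequency_binset` is an ordered list of inclusive period ranges in
#' seconds, longest periods first, over which spectral energies are summed
#' into one feature each. Ranges may leave gaps (coefficients there count
#' toward no bin). Where ranges touch or overlap, a coefficient is assigned
#' to the longer-period bin (deterministic tie-break).
#'
#' @param bins two-column matrix of `(period_hi_s, period_lo_s)` pairs.
#' @param name identifier for the bin set.
#' @return An object of class `frequency_binset`.
#' @export
frequency_binset <- function(bins, name = "custom") {
  bins <- matrix(as.numeric(bins), ncol = 2)
  if (nrow(bins) < 1L) stop("a binset needs at least one bin", call. = FALSE)
  if (any(!is.finite(bins)) || any(bins[, 2] <= 0))
    stop("bin period bounds must be finite and positive", call. = FALSE)
  if (any(bins[, 1] <= bins[, 2]))
    stop("each bin needs period_hi_s > period_lo_s", call. = FALSE)
  if (is.unsorted(rev(bins[, 1]), strictly = TRUE))
    stop("bins must be sorted by decreasing period", call. = FALSE)
  colnames(bins) <- c("period_hi_s", "period_lo_s")
  structure(list(name = name, bins = bins), class = "frequency_binset")
}

#' @export
print.frequency_binset <- function(x, ...) {
  cat(sprintf("frequency_binset '%s': %d bins spanning %g - %g s\n",
              x$name, nrow(x$bins), max(x$bins), min(x$bins)))
  invisible(x)
}

#' @export
length.frequency_binset <- function(x) nrow(x$bins)

#' Built-in frequency bin presets
#'
#' Three period-range presets for binning motion-parameter spectra:
#' `DANIO_XENOPUS_18` (18 bins, 598-0.1 s, for zebrafish and clawed-toad
#' embryos recorded at 15 fps), `RADIX_STAGE_18` (18 bins, for pond-snail
#' developmental-stage comparisons at 7.5 fps) and `RADIX_STRESSOR_30`
#' (30 bins, finer resolution for pond-snail environmental-stressor
#' comparisons).
#'
#' @param name one of `"DANIO_XENOPUS_18"`, `"RADIX_STAGE_18"`,
#'   `"RADIX_STRESSOR_30"`.
#' @return A [frequency_binset].
#' @export
preset <- function(name) {
  if (length(name) != 1L || !name %in% names(.binset_tables))
    stop("unknown binset preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(.binset_tables), collapse = ", "),
         call. = FALSE)
  frequency_binset(.binset_tables[[name]], name = name)
}

#' Read a custom bin set from a YAML config
#'
#' Expects a top-level `bins:` list of `[period_hi_s, period_lo_s]` pairs
#' and an optional `name:`.
#'
#' @param path YAML file path.
#' @return A [frequency_binset].
#' @export
read_binset <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$bins)) stop("binset config needs a 'bins' list", call. = FALSE)
  bins <- do.call(rbind, lapply(cfg$bins, function(b) as.numeric(unlist(b))))
  frequency_binset(bins, name = if (is.null(cfg$name)) "custom" else cfg$name)
}

#' Energy spectrum of a motion-parameter series
#'
#' Mean-centres the series (removing the DC term), applies the Discrete
#' Fourier Transform with a rectangular window, and reports one energy per
#' non-DC coefficient `k = 1 .. floor(N/2)`: `energy_k = (2/N^2) |X_k|^2`,
#' except that the Nyquist coefficient (even `N`) is not doubled. With this
#' normalization a unit-amplitude on-grid sinusoid carries energy 0.5.
#' Periods are `N / (k * fps)` seconds, strictly decreasing from `N/fps`
#' down to the two-sample period.
#'
#' @param series numeric vector, length >= 4.
#' @param fps sampling rate in Hz.
#' @return A list of class `spectrum`: `periods_s`, `energies`, `n_samples`,
#'   `fps`.
#' @export
dft_energy_spectrum <- function(series, fps) {
  n <- length(series)
  if (n < 4L)
    stop("insufficient samples: spectral analysis needs at least 4, got ", n,
         call. = FALSE)
  stopifnot(is.numeric(fps), fps > 0)
  x <- series - mean(series)
  X <- fft(x)
  k <- seq_len(n %/% 2L)
  energies <- (2 / n^2) * Mod(X[k + 1L])^2
  if (n %% 2L == 0L) energies[length(k)] <- energies[length(k)] / 2
  structure(list(periods_s = n / (k * fps), energies = energies,
                 n_samples = n, fps = fps),
            class = "spectrum")
}

#' Sum spectral energies into period bins
#'
#' Each bin value is the sum of the energies of all coefficients whose
#' period lies inside the bin's inclusive `[period_lo_s, period_hi_s]`
#' range. Coefficients falling in inter-bin gaps contribute to no bin;
#' where bins touch or overlap, a coefficient is counted once, in the
#' longer-period bin. Empty bins yield 0.
#'
#' @param spectrum a [dft_energy_spectrum] result.
#' @param binset a [frequency_binset].
#' @return Numeric vector of binned energies, one per bin.
#' @export
bin_energies <- function(spectrum, binset) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(binset, "frequency_binset"))
  p <- spectrum$periods_s
  e <- spectrum$energies
  taken <- logical(length(p))
  out <- numeric(nrow(binset$bins))
  for (i in seq_len(nrow(binset$bins))) {  # decreasing period = priority order
    inbin <- !taken & p >= binset$bins[i, 2] & p <= binset$bins[i, 1]
    out[i] <- sum(e[inbin])
    taken <- taken | inbin
  }
  out
}

#' Assemble a per-individual spectral feature vector
#'
#' Passes each of the four motion-parameter series through
#' [dft_energy_spectrum] and [bin_energies], concatenating the binned
#' energies in the fixed order pos_angle, neg_angle, com_rho, com_theta
#' (so an 18-bin preset yields 72 features, a 30-bin preset 120). Optionally
#' applies the `log(x + 1)` transform used before Bray-Curtis comparison.
#'
#' @param record a [motion_record].
#' @param binset a [frequency_binset].
#' @param log_transform apply `log(x + 1)` to every value (default `TRUE`).
#' @return A list of class `spectral_features`: `individual_id`, `values`
#'   (named numeric vector of length `4 * nbins`), `binset_name`,
#'   `log_transformed`.
#' @export
assemble_features <- function(record, binset, log_transform = TRUE) {
  stopifnot(inherits(record, "motion_record"), inherits(binset, "frequency_binset"))
  series <- list(pos_angle = record$pos_angle, neg_angle = record$neg_angle,
                 com_rho = record$com_rho, com_theta = record$com_theta)
  nb <- nrow(binset$bins)
  vals <- unlist(lapply(series, function(s)
    bin_energies(dft_energy_spectrum(s, record$fps), binset)), use.names = FALSE)
  if (log_transform) vals <- log(vals + 1)
  names(vals) <- paste0(rep(names(series), each = nb), ".",
                        sprintf("bin%02d", rep(seq_len(nb), 4L)))
  structure(list(individual_id = record$source_id, values = vals,
                 binset_name = binset$name, log_transformed = log_transform),
            class = "spectral_features")
}

#' Stack feature vectors into a matrix
#'
#' @param features list of `spectral_features` from [assemble_features].
#' @return Numeric matrix, rows = individuals (named by `individual_id`),
#'   columns = binset-qualified feature names.
#' @export
feature_matrix <- function(features) {
  stopifnot(length(features) >= 1L,
            all(vapply(features, inherits, logical(1), "spectral_features")))
  lens <- vapply(features, function(f) length(f$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("feature vectors have differing lengths; were different binsets used?",
         call. = FALSE)
  m <- do.call(rbind, lapply(features, function(f) f$values))
  rownames(m) <- vapply(features, function(f) f$individual_id, character(1))
  m
}

#' Write/read a feature matrix as CSV
#'
#' Rows are individuals (first column `id`), columns are binset-qualified
#' feature names such as `pos_angle.bin01`.
#'
#' @param m feature matrix from [feature_matrix].
#' @param path CSV path.
#' @return [write_feature_csv]: `path` invisibly; [read_feature_csv]: a
#'   numeric matrix with individual ids as rownames.
#' @export
write_feature_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"id" %in% names(df)) stop("feature CSV needs an 'id' column", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric feature values in '", path, "'", call. = FALSE)
  rownames(m) <- df$id
  m
}
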