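# Deterministic preprocessing: clinical encoding with explicit missingness
# handling, and volume size/intensity normalization.  Statistics used for
# encoding are always fitted on the training split only.

#' Fit clinical normalization statistics on a training split
#'
#' Computes the age mean and SD over observed (non-missing) ages.  The SD
#' uses the sample (n-1) convention by default; set
#' `sd_convention = "population"` for the n denominator.
#'
#' @param records data.frame with at least an `age` column (NA = missing).
#' @param sd_convention `"sample"` (default) or `"population"`.
#' @return list of class `clinical_stats` with `age_mean`, `age_sd`,
#'   `degenerate` (TRUE when the observed ages have zero spread).
#' @export
fit_clinical_stats <- function(records, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  ages <- records$age
  ages <- ages[!is.na(ages)]
  stop_if_not(length(ages) >= 2, "need >= 2 records with observed age")
  m <- mean(ages)
  s <- stats::sd(ages)
  if (sd_convention == "population") s <- s * sqrt((length(ages) - 1) / length(ages))
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) s <- 1  # keep encoding total; flagged for the caller
  structure(list(age_mean = m, age_sd = s, degenerate = degenerate,
                 sd_convention = sd_convention),
            class = "clinical_stats")
}

#' Layout of the encoded clinical vector
#'
#' Fixed slot order: standardized age, race one-hot over `K_race + 1` slots
#' (last slot = missing), ER, PR, HR, HER2 (each passed through with -1
#' denoting missing), and subtype one-hot over `K_subtype + 1` slots.
#'
#' @param K_race,K_subtype number of valid categories for race and
#'   molecular subtype (missing maps to the extra index `K`).
#' @return list with slot names, block indices and total length.
#' @export
clinical_layout <- function(K_race = 3L, K_subtype = 4L) {
  len <- 1L + (K_race + 1L) + 4L + (K_subtype + 1L)
  list(K_race = K_race, K_subtype = K_subtype, length = len,
       slots = c("age",
                 paste0("race_", c(seq_len(K_race) - 1L, "missing")),
                 "er", "pr", "hr", "her2",
                 paste0("subtype_", c(seq_len(K_subtype) - 1L, "missing"))))
}

encode_one_hot <- function(code, K) {
  v <- numeric(K + 1L)
  if (!is.na(code)) {
    stop_if_not(code >= 0 && code < K,
                "categorical code %s out of range [0,%d)",
                as.character(code), K)
  }
  idx <- if (is.na(code)) K else code
  v[idx + 1L] <- 1
  v
}

#' Encode one clinical record as a fixed-length numeric vector
#'
#' Age is Z-scored with training-split statistics (-1 when missing);
#' binary markers pass through with -1 for missing; race and subtype are
#' one-hot encoded over `K + 1` categories with missing mapped to the
#' extra index `K`.
#'
#' @param record one-row data.frame or named list with fields
#'   `age, race, er, pr, hr, her2, subtype` (NA = missing).
#' @param stats a [fit_clinical_stats()] result.
#' @param K_race,K_subtype category counts (defaults match the synthetic
#'   generator).
#' @return numeric vector of length `clinical_layout()$length`.
#' @export
encode_clinical <- function(record, stats, K_race = 3L, K_subtype = 4L) {
  stop_if_not(inherits(stats, "clinical_stats"), "`stats` must come from fit_clinical_stats()")
  age <- record[["age"]]
  age_slot <- if (is.na(age)) -1 else (age - stats$age_mean) / stats$age_sd
  bin <- vapply(c("er", "pr", "hr", "her2"), function(nm) {
    v <- record[[nm]]
    if (is.na(v)) -1 else as.numeric(v)
  }, numeric(1))
  out <- c(age_slot,
           encode_one_hot(record[["race"]], K_race),
           bin,
           encode_one_hot(record[["subtype"]], K_subtype))
  names(out) <- clinical_layout(K_race, K_subtype)$slots
  out
}

#' Encode a whole clinical table
#'
#' @param records data.frame of raw records.
#' @inheritParams encode_clinical
#' @return numeric matrix, one encoded row per record, with the layout's
#'   slot names as column names.
#' @export
encode_clinical_table <- function(records, stats, K_race = 3L, K_subtype = 4L) {
  lay <- clinical_layout(K_race, K_subtype)
  out <- matrix(0, nrow(records), lay$length,
                dimnames = list(NULL, lay$slots))
  for (i in seq_len(nrow(records))) {
    out[i, ] <- encode_clinical(records[i, , drop = FALSE], stats,
                                K_race, K_subtype)
  }
  out
}

#' Pad and crop a volume to a target shape
#'
#' Symmetric zero padding (odd remainders put the extra voxel on the
#' high-index side) followed by central cropping, so any input shape maps
#' to exactly `target`.  The operation is idempotent at the target shape.
#'
#' @param volume 3D array.
#' @param target integer length-3 target shape (H, W, D).
#' @return 3D array of dimension `target`.
#' @export
pad_crop_volume <- function(volume, target = c(192L, 192L, 112L)) {
  stop_if_not(is.array(volume) && length(dim(volume)) == 3L,
              "`volume` must be a 3D array")
  src <- dim(volume)
  target <- as.integer(target)

  # pad up to at least the target
  pad_lo <- integer(3); pad_hi <- integer(3)
  for (ax in 1:3) {
    need <- max(0L, target[ax] - src[ax])
    pad_lo[ax] <- need %/% 2L
    pad_hi[ax] <- need - pad_lo[ax]
  }
  padded <- array(0, dim = src + pad_lo + pad_hi)
  padded[pad_lo[1] + seq_len(src[1]),
         pad_lo[2] + seq_len(src[2]),
         pad_lo[3] + seq_len(src[3])] <- volume

  # central crop down to the target
  pd <- dim(padded)
  off <- (pd - target) %/% 2L
  padded[off[1] + seq_len(target[1]),
         off[2] + seq_len(target[2]),
         off[3] + seq_len(target[3]), drop = FALSE]
}

#' Z-score normalize a volume
#'
#' Standardizes all voxels jointly to mean 0 / SD 1 (population SD).  A
#' constant (zero-variance) volume returns all zeros, the documented
#' convention for degenerate inputs.
#'
#' @param volume 3D array.
#' @return 3D array of the same shape.
#' @export
zscore_volume <- function(volume) {
  stop_if_not(length(volume) > 0, "empty volume")
  m <- mean(volume)
  s <- sqrt(mean((volume - m)^2))
  if (!is.finite(s) || s == 0) return(volume * 0)
  (volume - m) / s
}
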