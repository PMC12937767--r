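# Clinical metadata module: train-fitted standardization and binary encoding
# of the 12-field clinical record (age, gender, two lesion diameters, two
# lifestyle flags, six symptom flags).

meta_continuous <- c("age", "diameter_1", "diameter_2")
meta_binary <- c("smoke", "drink", "itch", "grew", "hurt", "changed",
                 "bleed", "elevation")

metadata_feature_names <- function() {
  c("age_z", "gender", "d1_z", "d2_z", meta_binary)
}

# Coerce assorted truthy encodings ("True", "TRUE", 1, TRUE) to logical.
as_binary_flag <- function(x, field) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) abort(sprintf("field '%s': numeric flags must be 0/1", field))
    return(as.logical(x))
  }
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("TRUE", "T", "YES", "1")] <- TRUE
  out[s %in% c("FALSE", "F", "NO", "0")] <- FALSE
  out[is.na(x) | s == "" | s == "NA"] <- NA
  bad <- is.na(out) & !(is.na(x) | s == "" | s == "NA")
  if (any(bad)) {
    abort(sprintf("field '%s': unrecognized flag value '%s'", field,
                  as.character(x)[which(bad)[1]]))
  }
  out
}

encode_gender <- function(x) {
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA_real_, length(s))
  out[s %in% c("MALE", "M")] <- 1
  out[s %in% c("FEMALE", "F")] <- 0
  unknown <- !is.na(x) & s != "" & s != "NA" & is.na(out)
  if (any(unknown)) {
    abort(sprintf(
      "unknown gender token '%s'; accepted: Male, Female (or M/F)",
      as.character(x)[which(unknown)[1]]
    ))
  }
  out
}

#' Fit metadata standardization statistics on the training partition
#'
#' Computes, per continuous field (age and the two lesion diameters), the
#' mean and population standard deviation over non-missing training values,
#' plus the training median used for imputation. Statistics must be fitted on
#' the training split only so that test-set encoding never leaks test
#' information.
#'
#' @param train_records Data frame with columns `age`, `gender`,
#'   `diameter_1`, `diameter_2` and the eight binary flags.
#' @param eps Stabilizer added to the standard deviation. Default 1e-8.
#' @return Object of class `metadata_stats`.
#' @export
fit_metadata_stats <- function(train_records, eps = 1e-8) {
  train_records <- tibble::as_tibble(train_records)
  if (nrow(train_records) < 2) abort("need at least 2 training records")
  stats <- purrr::map(meta_continuous, function(f) {
    if (!f %in% names(train_records)) {
      abort(sprintf("metadata field '%s' missing from training records", f))
    }
    v <- suppressWarnings(as.numeric(train_records[[f]]))
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      abort(sprintf("metadata field '%s' is entirely missing in train", f))
    }
    list(
      mean = mean(v),
      sd = sqrt(mean((v - mean(v))^2)),  # population sd
      median = stats::median(v),
      n = length(v)
    )
  })
  names(stats) <- meta_continuous
  structure(
    list(fields = stats, eps = eps, n_train = nrow(train_records)),
    class = "metadata_stats"
  )
}

#' @export
print.metadata_stats <- function(x, ...) {
  cat("<metadata_stats> fitted on", x$n_train, "training records\n")
  for (f in names(x$fields)) {
    s <- x$fields[[f]]
    cat(sprintf("  %-10s mean %.3f  sd %.3f  median %.3f  (n = %d)\n",
                f, s$mean, s$sd, s$median, s$n))
  }
  invisible(x)
}

#' Encode clinical metadata records as 12-d feature rows
#'
#' Continuous fields are z-scored with train-fitted statistics,
#' `(x - mean) / (sd + eps)`; gender is encoded Male = 1, Female = 0; binary
#' flags become 0/1. Missing continuous values are imputed with the training
#' median before z-scoring; missing binary values become 0. The number of
#' imputations is reported once per call.
#'
#' @param records Data frame of metadata records (see [fit_metadata_stats()]).
#' @param stats Fitted `metadata_stats` object.
#' @return Tibble with 12 columns in the fixed order `age_z`, `gender`,
#'   `d1_z`, `d2_z`, `smoke`, `drink`, `itch`, `grew`, `hurt`, `changed`,
#'   `bleed`, `elevation`, one row per record.
#' @export
encode_metadata <- function(records, stats) {
  if (!inherits(stats, "metadata_stats")) {
    abort("`stats` must come from fit_metadata_stats()")
  }
  records <- tibble::as_tibble(records)
  n_imputed <- 0L

  zscore <- function(field) {
    v <- suppressWarnings(as.numeric(records[[field]]))
    s <- stats$fields[[field]]
    miss <- is.na(v)
    n_imputed <<- n_imputed + sum(miss)
    v[miss] <- s$median
    (v - s$mean) / (s$sd + stats$eps)
  }
  flag01 <- function(field) {
    v <- as_binary_flag(records[[field]], field)
    miss <- is.na(v)
    n_imputed <<- n_imputed + sum(miss)
    v[miss] <- FALSE
    as.numeric(v)
  }

  gender <- encode_gender(records$gender)
  gmiss <- is.na(gender)
  n_imputed <- n_imputed + sum(gmiss)
  gender[gmiss] <- 0

  out <- tibble::tibble(
    age_z = zscore("age"),
    gender = gender,
    d1_z = zscore("diameter_1"),
    d2_z = zscore("diameter_2")
  )
  for (f in meta_binary) out[[f]] <- flag01(f)
  if (n_imputed > 0) {
    rlang::inform(sprintf("encode_metadata: imputed %d missing values", n_imputed))
  }
  out
}

#' Canonicalize a metadata table from dataset-specific headers
#'
#' Renames columns of a clinical metadata CSV to the canonical schema used
#' throughout the package (`image_id`, `patient_id`, `label`, `age`,
#' `gender`, `diameter_1`, `diameter_2` and the eight binary flags). The
#' default mapping covers the header names common in public clinical
#' lesion datasets (`img_id`, `diagnostic`, `diameter_1/2`); pass `mapping`
#' entries of the form `c(canonical = "source_header")` to adapt others.
#'
#' @param records Data frame read from a metadata CSV.
#' @param mapping Named character vector, canonical name -> source header.
#' @return Tibble with canonical column names (unmapped extra columns are
#'   kept as-is).
#' @export
canonicalize_metadata <- function(records,
                                  mapping = c(image_id = "img_id",
                                              label = "diagnostic")) {
  records <- tibble::as_tibble(records)
  for (canon in names(mapping)) {
    src <- mapping[[canon]]
    if (canon %in% names(records)) next
    if (!src %in% names(records)) {
      abort(sprintf("cannot map '%s': column '%s' not found", canon, src))
    }
    names(records)[names(records) == src] <- canon
  }
  records
}
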