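# The 14-variable spectral index set: 7 raw indices computed from
# hospital-normalized channel means, plus the same 7 divided by their
# overall (pooled) means.

#' Compute the 7 raw spectral indices from channel means
#'
#' Given per-ROI mean channel intensities, returns
#' `R, G, B, R-B, R-G, (R-B)/G, (R-B)/(R^2+B^2)`. A zero denominator yields
#' `NA` for that index (the record is retained; the value is excluded from
#' statistics on that variable), never infinity.
#'
#' @param r,g,b channel means, or `r` may be a named vector/list with
#'   elements `r`, `g`, `b`.
#' @return named numeric vector of length 7 (names [raw_index_names()]).
#' @export
compute_raw_indices <- function(r, g = NULL, b = NULL) {
  if (is.null(g)) {
    m <- r
    r <- m[["r"]]; g <- m[["g"]]; b <- m[["b"]]
  }
  stopifnot(is.finite(r), is.finite(g), is.finite(b))
  out <- c(
    r = r, g = g, b = b,
    r_minus_b = r - b,
    r_minus_g = r - g,
    rb_over_g = if (g == 0) NA_real_ else (r - b) / g,
    rb_over_r2b2 = if (r^2 + b^2 == 0) NA_real_ else (r - b) / (r^2 + b^2)
  )
  out
}

#' Fit the cohort normalization reference
#'
#' Two-level normalization. First, each image's mean R, G, B are divided by
#' that hospital's mean channel values and rescaled onto a fixed reference
#' tone (a nominal well-perfused wound-bed color), which removes
#' camera/lighting gain differences between operating rooms exactly — the
#' hospital mean absorbs any per-channel gain — while keeping the channels
#' on a familiar intensity scale. (Rescaling each hospital to exactly mean 1
#' instead would force every difference composite such as R-G to average
#' zero over the fit population, making the second normalization
#' degenerate; a data-derived grand mean would re-introduce a gain
#' dependence.) The 7 raw indices are computed from these
#' hospital-normalized channels; each index is then divided by its overall
#' mean pooled across the fit population, so every normalized variable
#' averages 1 there.
#'
#' @param channels data frame with columns `hospital`, `r`, `g`, `b` (one row
#'   per image, values from [roi_channel_means()]).
#' @param reference_tone fixed per-channel constants the hospital-normalized
#'   channels are scaled onto; a method constant, not fitted from data.
#' @return object of class `ccd_normalizer` holding per-hospital channel
#'   means, the reference tone, pooled per-variable means, and the fit
#'   population size.
#' @export
fit_normalizer <- function(channels,
                           reference_tone = c(r = 0.75, g = 0.60, b = 0.35)) {
  req <- c("hospital", "r", "g", "b")
  miss <- setdiff(req, names(channels))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(channels) < 1) stop("no records to fit the normalizer on")
  hosp <- split(channels[, c("r", "g", "b")], channels$hospital)
  hospital_means <- lapply(hosp, function(d) {
    m <- colMeans(d)
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop("non-positive hospital channel mean; cannot normalize")
    }
    m
  })
  stopifnot(all(reference_tone > 0), length(reference_tone) == 3)
  raw <- raw_index_table(channels, hospital_means, reference_tone)
  variable_means <- colMeans(raw, na.rm = TRUE)
  if (any(variable_means == 0, na.rm = TRUE)) {
    bad <- raw_index_names()[which(variable_means == 0)]
    stop("overall mean of variable(s) ", paste(bad, collapse = ", "),
         " is zero; cannot normalize")
  }
  structure(list(hospital_means = hospital_means,
                 reference_tone = reference_tone,
                 variable_means = variable_means,
                 n = nrow(channels)),
            class = "ccd_normalizer")
}

# Hospital-normalize channels (onto the fixed reference tone) and compute
# the 7 raw indices, one row per record.
raw_index_table <- function(channels, hospital_means, reference_tone) {
  t(vapply(seq_len(nrow(channels)), function(i) {
    h <- as.character(channels$hospital[i])
    hm <- hospital_means[[h]]
    if (is.null(hm)) stop("unknown hospital cohort '", h, "'")
    compute_raw_indices(channels$r[i] * reference_tone[["r"]] / hm[["r"]],
                        channels$g[i] * reference_tone[["g"]] / hm[["g"]],
                        channels$b[i] * reference_tone[["b"]] / hm[["b"]])
  }, numeric(7)))
}

#' Divide raw indices by their overall means
#'
#' @param raw named length-7 vector of raw indices (hospital-normalized
#'   scale, as produced under a [fit_normalizer()] reference).
#' @param ref a `ccd_normalizer`.
#' @return list with `raw` and `normalized`, each a named length-7 vector
#'   (the 14-variable feature set).
#' @export
normalize_features <- function(raw, ref) {
  stopifnot(inherits(ref, "ccd_normalizer"), length(raw) == 7)
  normalized <- raw / ref$variable_means[raw_index_names()]
  names(normalized) <- paste0(raw_index_names(), "_norm")
  list(raw = raw, normalized = normalized)
}

#' Build the per-image feature table
#'
#' Applies the fitted normalization reference to per-image channel means and
#' returns one row per image with the 14 spectral variables plus any
#' passthrough metadata columns present in the input.
#'
#' @param channels data frame with columns `hospital`, `r`, `g`, `b` plus
#'   optional metadata columns (e.g. `image_id`, `outcome`, covariates).
#' @param ref a [fit_normalizer()] reference.
#' @return data frame: metadata columns, then the 7 raw index columns, then
#'   the 7 `_norm` columns.
#' @export
extract_features <- function(channels, ref) {
  stopifnot(inherits(ref, "ccd_normalizer"))
  raw <- raw_index_table(channels, ref$hospital_means, ref$reference_tone)
  colnames(raw) <- raw_index_names()
  normed <- sweep(raw, 2, ref$variable_means[raw_index_names()], "/")
  colnames(normed) <- paste0(raw_index_names(), "_norm")
  meta <- channels[, setdiff(names(channels), c("r", "g", "b")), drop = FALSE]
  cbind(meta, as.data.frame(raw), as.data.frame(normed))
}

# Canonical order of the 17 model predictors.
predictor_names <- function() {
  c(raw_index_names(), paste0(raw_index_names(), "_norm"),
    "wound_area_cm2", "days_post_injury", "age")
}

#' Assemble the 17-variable model input
#'
#' Concatenates the 14 spectral variables with wound surface area, days post
#' injury and patient age in a fixed canonical order.
#'
#' @param fv a [normalize_features()] result (list with `raw` and
#'   `normalized`).
#' @param record list or one-row data frame with `wound_area_cm2`,
#'   `days_post_injury`, `age` (and optionally `outcome`).
#' @return named numeric vector of length 17; the outcome label, when
#'   present, is attached as attribute `outcome`.
#' @export
assemble_model_input <- function(fv, record) {
  covars <- c("wound_area_cm2", "days_post_injury", "age")
  vals <- lapply(covars, function(nm) record[[nm]])
  bad <- covars[vapply(vals, function(v) is.null(v) || length(v) != 1 ||
                         is.na(v), logical(1))]
  if (length(bad)) {
    stop("incomplete record: missing covariate(s) ",
         paste(bad, collapse = ", "))
  }
  x <- c(fv$raw[raw_index_names()],
         fv$normalized[paste0(raw_index_names(), "_norm")],
         wound_area_cm2 = as.numeric(record$wound_area_cm2),
         days_post_injury = as.numeric(record$days_post_injury),
         age = as.numeric(record$age))
  names(x) <- predictor_names()
  if (!is.null(record$outcome)) attr(x, "outcome") <- as.character(record$outcome)
  x
}

#' Serialize a normalization reference to JSON
#'
#' @param ref a `ccd_normalizer`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_normalizer <- function(ref, path) {
  stopifnot(inherits(ref, "ccd_normalizer"))
  write_atomic(path, function(tmp) {
    jsonlite::write_json(
      list(hospital_means = lapply(ref$hospital_means, as.list),
           reference_tone = as.list(ref$reference_tone),
           variable_means = as.list(ref$variable_means), n = ref$n),
      tmp, auto_unbox = TRUE, digits = NA)
  })
}

#' Read a normalization reference from JSON
#'
#' @param path JSON path written by [write_normalizer()].
#' @return a `ccd_normalizer`.
#' @export
read_normalizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(hospital_means = lapply(x$hospital_means, unlist),
                 reference_tone = unlist(x$reference_tone),
                 variable_means = unlist(x$variable_means), n = x$n),
            class = "ccd_normalizer")
}
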