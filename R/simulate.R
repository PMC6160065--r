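# Synthetic wound cohorts: a Beer-Lambert hemoglobin-absorption model maps a
# latent tissue oxygen saturation (StO2) to wound-bed R/G/B reflectance;
# hierarchical patient -> wound -> débridement sampling emulates the
# structure of a two-hospital traumatic-wound study.

#' Optical parameters of the wound-bed reflectance model
#'
#' Wound-bed intensity in channel c is
#' `gain_c * L_c * exp(-(sto2 * eps_oxy_c + (1 - sto2) * eps_deoxy_c) * chb)`.
#' The extinction coefficients are approximate effective absorbances
#' (dimensionless, already folded with the molar scale and optical path at
#' `chb = 1`) at nominal effective wavelengths of roughly 610 nm (R), 545 nm
#' (G) and 450 nm (B). They are not a spectroscopic tabulation; the contract
#' is the ordering that drives the index directions: deoxyhemoglobin absorbs
#' more than oxyhemoglobin in every channel, by far the most strongly in
#' red, so R-B rises with StO2 while (R-B)/(R^2+B^2) falls.
#'
#' @param eps_oxy,eps_deoxy named length-3 vectors (r, g, b) of effective
#'   extinction coefficients for oxy- and deoxyhemoglobin.
#' @param chb total hemoglobin concentration scale (unitless multiplier).
#' @param illumination per-channel illumination weights.
#' @return list of class `optical_params`.
#' @export
optical_params <- function(eps_oxy = c(r = 0.10, g = 0.35, b = 0.95),
                           eps_deoxy = c(r = 0.45, g = 0.50, b = 1.10),
                           chb = 1,
                           illumination = c(r = 0.95, g = 0.95, b = 0.95)) {
  stopifnot(all(eps_oxy > 0), all(eps_deoxy > 0), chb > 0,
            all(illumination > 0))
  if (eps_deoxy[["r"]] <= eps_oxy[["r"]]) {
    stop("deoxyhemoglobin extinction in the red channel must exceed ",
         "oxyhemoglobin's (this ordering drives the R-B direction)")
  }
  structure(list(eps_oxy = eps_oxy, eps_deoxy = eps_deoxy, chb = chb,
                 illumination = illumination),
            class = "optical_params")
}

# Wound-bed reflectance per channel for a saturation value.
wound_reflectance <- function(sto2, optics) {
  mu <- sto2 * optics$eps_oxy + (1 - sto2) * optics$eps_deoxy
  optics$illumination * exp(-mu * optics$chb)
}

#' Render one synthetic wound photograph
#'
#' Draws an elliptical wound bed over a textured skin-toned background. Bed
#' pixels follow the Beer-Lambert channel model for the given StO2 with
#' multiplicative pixel noise; the per-channel camera gain multiplies the
#' whole unclipped scene (so doubling the gain exactly doubles ROI channel
#' means before clipping). Deterministic for a given seed.
#'
#' @param sto2 tissue oxygen saturation in `[0, 1]`.
#' @param optics an [optical_params()] list.
#' @param gain per-channel camera gain multipliers (length 3, > 0).
#' @param noise_sd multiplicative pixel noise standard deviation.
#' @param seed RNG seed.
#' @param size image side length in pixels (square image).
#' @return list with `image` (an [rgb_image()]) and `mask` (the wound-bed
#'   ROI, logical matrix).
#' @export
render_wound_image <- function(sto2, optics = optical_params(),
                               gain = c(1, 1, 1), noise_sd = 0.01,
                               seed = 1, size = 128) {
  stopifnot(sto2 >= 0, sto2 <= 1, all(gain > 0), size >= 16)
  local_seed(seed, {
    h <- w <- as.integer(size)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- h / 2 + stats::runif(1, -0.04, 0.04) * h
    cx <- w / 2 + stats::runif(1, -0.04, 0.04) * w
    a <- stats::runif(1, 0.24, 0.30) * w  # semi-axis, x
    b <- stats::runif(1, 0.16, 0.22) * h  # semi-axis, y
    mask <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1
    skin <- c(0.80, 0.62, 0.52)
    bed <- wound_reflectance(sto2, optics)
    scene <- array(0, dim = c(h, w, 3))
    grad <- 1 + 0.05 * (rows - h / 2) / h  # gentle illumination gradient
    for (c in 1:3) {
      layer <- skin[c] * grad * (1 + stats::rnorm(h * w, 0, noise_sd))
      layer[mask] <- bed[c] * (1 + stats::rnorm(sum(mask), 0, noise_sd))
      scene[, , c] <- gain[c] * layer
    }
    list(image = rgb_image(pmin(pmax(scene, 0), 1)), mask = mask)
  })
}

#' Inject a quality-control artifact into an image
#'
#' `glare` paints saturated specular discs covering about `severity` of the
#' ROI; `blur` applies a Gaussian blur with sigma scaling with severity (up
#' to 6 px); `blood` paints dark-red patches covering about `severity` of
#' the ROI. Severity 0 returns the image unchanged.
#'
#' @param image an [rgb_image()].
#' @param kind `"glare"`, `"blur"` or `"blood"`.
#' @param severity artifact strength in `[0, 1]`.
#' @param seed RNG seed.
#' @param roi logical mask locating the wound bed (defaults to the whole
#'   image for area bookkeeping).
#' @return the modified `rgb_image`.
#' @export
inject_artifacts <- function(image, kind, severity, seed = 1, roi = NULL) {
  stopifnot(inherits(image, "rgb_image"), severity >= 0, severity <= 1)
  kind <- match.arg(kind, c("glare", "blur", "blood"))
  if (severity == 0) return(image)
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  if (kind == "blur") {
    sigma <- severity * 6
    # brush must be odd and fit inside the image
    radius <- min(2 * ceiling(3 * sigma) + 1,
                  2 * floor((min(h, w) - 2) / 2) + 1)
    img <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
    blurred <- EBImage::imageData(EBImage::gblur(img, sigma = sigma,
                                                 radius = radius))
    return(rgb_image(pmin(pmax(aperm(blurred, c(2, 1, 3)), 0), 1)))
  }
  # Disc-shaped overlay inside the ROI covering ~severity of its area,
  # centered at the ROI centroid (so it stays inside a convex ROI).
  idx <- which(roi, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  target <- severity * nrow(idx)
  radius <- sqrt(target / pi)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  jitter <- local_seed(seed, stats::runif(2, -0.1, 0.1) * radius)
  disc <- ((rows - cy - jitter[1])^2 + (cols - cx - jitter[2])^2) <= radius^2
  disc <- disc & roi
  if (kind == "glare") {
    for (c in 1:3) { l <- px[, , c]; l[disc] <- 1; px[, , c] <- l }
  } else { # blood
    col <- c(0.45, 0.07, 0.06)
    for (c in 1:3) { l <- px[, , c]; l[disc] <- col[c]; px[, , c] <- l }
  }
  rgb_image(px)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of the clinical study the analysis is
#' designed for: two hospital cohorts with different camera gains (roughly
#' 73/27 patient split), about 1.45 wounds per patient and 2.7 débridement
#' images per wound (so ~66 patients yield on the order of 250-300 images),
#' wound-level outcomes at 20% dehiscence, delayed healing defined by
#' closure after day 21, and per-class StO2 distributions through which the
#' optical model drives the spectral indices.
#'
#' @param n_patients number of patients.
#' @param n_wounds optional exact wound count (overrides per-patient
#'   sampling).
#' @param class_props named proportions for `healed`, `delayed`, `dehisced`
#'   (must sum to 1); wounds are assigned exactly by largest remainder.
#' @param sto2_mean,sto2_sd per-class StO2 distribution parameters.
#' @param sto2_drift per-class StO2 change per débridement index (healing
#'   wounds reperfuse; dehiscing wounds deteriorate).
#' @param hospitals named patient-assignment weights.
#' @param hospital_gains named list of per-channel gain vectors.
#' @param wounds_per_patient_mean,debridements_mean Poisson-like means for
#'   the hierarchy (each at least 1 per unit); `debridements_mean` sets the
#'   débridement count of a 15-day wound, and wounds that stay open longer
#'   accrue proportionally more.
#' @param closure_mean,closure_sd per-class closure-day distributions:
#'   healed closes by day 21, delayed healing is defined by closure after
#'   day 21, and dehisced wounds are typically closed early (premature
#'   closure preceding failure). Débridement imaging stops at closure.
#' @param artifact_rates named per-image probabilities for `glare`, `blur`,
#'   `blood` artifacts.
#' @param area_meanlog,area_sdlog,area_min lognormal wound surface area
#'   (cm^2) parameters, truncated below at the study's 75 cm^2 entry size.
#' @param age_mean,age_sd patient age distribution (truncated to 18-80).
#' @param image_size image side length in pixels.
#' @param noise_sd pixel noise for the renderer.
#' @param optics an [optical_params()] list.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 66,
                          n_wounds = NULL,
                          class_props = c(healed = 0.55, delayed = 0.25,
                                          dehisced = 0.20),
                          sto2_mean = c(healed = 0.75, delayed = 0.62,
                                        dehisced = 0.45),
                          sto2_sd = 0.08,
                          sto2_drift = c(healed = 0.02, delayed = 0.008,
                                         dehisced = -0.02),
                          hospitals = c(grady = 0.73, wrnmmc = 0.27),
                          hospital_gains = list(grady = c(1, 1, 1),
                                                wrnmmc = c(1.08, 1.06, 0.92)),
                          wounds_per_patient_mean = 1.45,
                          debridements_mean = 2.7,
                          closure_mean = c(healed = 15, delayed = 28,
                                           dehisced = 11),
                          closure_sd = c(healed = 3, delayed = 4,
                                         dehisced = 2),
                          artifact_rates = c(glare = 0.04, blur = 0.04,
                                             blood = 0.04),
                          area_meanlog = log(150), area_sdlog = 0.5,
                          area_min = 75,
                          age_mean = 40, age_sd = 15,
                          image_size = 128, noise_sd = 0.01,
                          optics = optical_params()) {
  stopifnot(abs(sum(class_props) - 1) < 1e-8,
            all(class_props >= 0),
            all(artifact_rates >= 0), all(artifact_rates <= 1),
            setequal(names(class_props), outcome_levels()),
            setequal(names(hospitals), names(hospital_gains)))
  structure(as.list(environment()), class = "cohort_config")
}

#' Delayed-confound evaluation scenario
#'
#' A [cohort_config()] preset in which delayed-healing wounds are
#' spectrally indistinguishable from dehisced wounds (same StO2 mean and
#' drift) and differ only temporally: delayed wounds stay open past day 21
#' while dehisced wounds are closed prematurely. A single flat classifier of
#' dehisced-versus-rest cannot separate the two low-StO2 classes, whereas
#' the sequential model can first remove delayed wounds on their
#' débridement-day signature and then apply a clean spectral rule — the
#' structural situation the two-stage design exists for. Artifact injection
#' is disabled so model comparisons are not confounded by quality screening.
#'
#' @param ... overrides passed on to [cohort_config()].
#' @return a `cohort_config`.
#' @export
cohort_config_confounded <- function(...) {
  cohort_config(
    sto2_mean = c(healed = 0.75, delayed = 0.45, dehisced = 0.45),
    sto2_drift = c(healed = 0.02, delayed = -0.02, dehisced = -0.02),
    closure_mean = c(healed = 15, delayed = 28, dehisced = 15),
    closure_sd = c(healed = 3, delayed = 4, dehisced = 3),
    artifact_rates = c(glare = 0, blur = 0, blood = 0),
    ...)
}

# Exact integer class counts by largest remainder.
largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Sample a labeled synthetic cohort
#'
#' Hierarchical sampling of patients, wounds and débridements. Outcomes are
#' assigned at the wound level with exact class proportions (largest
#' remainder). Each image's StO2 is its wound's class mean plus a wound
#' offset, class drift over débridement index, and image noise; images are
#' rendered with the hospital's camera gain and artifacts injected at the
#' configured rates. Delayed-healing wounds close after day 21, so their
#' débridement days extend past 21.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; the run is fully deterministic given it.
#' @param render if `FALSE`, skip image rendering and derive channel means
#'   directly from the optical model plus sampling noise (fast path for
#'   large statistical experiments; metadata is identical).
#' @return list of class `synthetic_cohort`: `images`, `masks` (lists, empty
#'   on the fast path), `metadata` (one row per image: ids, hospital,
#'   covariates, outcome, `true_sto2`, and on the fast path `r`, `g`, `b`),
#'   and `config`.
#' @export
sample_cohort <- function(config = cohort_config(), seed = 1,
                          render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  meta <- local_seed(seed, sample_cohort_metadata(config))
  images <- list(); masks <- list()
  if (render) {
    for (i in seq_len(nrow(meta))) {
      rw <- render_wound_image(
        meta$true_sto2[i], optics = config$optics,
        gain = config$hospital_gains[[meta$hospital[i]]],
        noise_sd = config$noise_sd,
        seed = child_seed(seed, i), size = config$image_size)
      img <- rw$image
      if (meta$artifact[i] != "none") {
        img <- inject_artifacts(img, meta$artifact[i],
                                severity = meta$artifact_severity[i],
                                seed = child_seed(seed, i) + 1,
                                roi = rw$mask)
      }
      images[[i]] <- img
      masks[[i]] <- rw$mask
    }
  } else {
    refl <- t(vapply(meta$true_sto2, wound_reflectance, numeric(3),
                     optics = config$optics))
    gains <- t(vapply(meta$hospital,
                      function(hh) config$hospital_gains[[hh]], numeric(3)))
    noise <- local_seed(child_seed(seed, 999983),
                        matrix(stats::rnorm(3 * nrow(meta), 0,
                                            config$noise_sd / 4),
                               ncol = 3))
    ch <- pmin(pmax(gains * refl * (1 + noise), 0), 1)
    meta$r <- ch[, 1]; meta$g <- ch[, 2]; meta$b <- ch[, 3]
  }
  structure(list(images = images, masks = masks, metadata = meta,
                 config = config),
            class = "synthetic_cohort")
}

# Metadata-level sampling; assumes the RNG is already seeded.
sample_cohort_metadata <- function(config) {
  n_pat <- config$n_patients
  pat_hospital <- sample(names(config$hospitals), n_pat, replace = TRUE,
                         prob = config$hospitals)
  pat_age <- pmin(80, pmax(18, round(stats::rnorm(n_pat, config$age_mean,
                                                  config$age_sd))))
  if (is.null(config$n_wounds)) {
    wounds_per <- 1 + stats::rpois(n_pat, config$wounds_per_patient_mean - 1)
  } else {
    wounds_per <- largest_remainder(
      config$n_wounds, stats::setNames(rep(1 / n_pat, n_pat),
                                       paste0("p", seq_len(n_pat))))
  }
  wound_patient <- rep(seq_len(n_pat), wounds_per)
  n_wounds <- length(wound_patient)
  if (n_wounds < 3) stop("cohort too small: fewer than 3 wounds")
  counts <- largest_remainder(n_wounds,
                              config$class_props[outcome_levels()])
  if (any(counts == 0)) {
    stop("infeasible class proportions for ", n_wounds, " wounds")
  }
  outcome <- sample(rep(outcome_levels(), counts))
  # Closure day per class: healed wounds close by day 21, delayed healing is
  # defined by closure after day 21, and dehisced wounds are typically closed
  # early (premature closure preceding failure).
  cm <- config$closure_mean; cs <- config$closure_sd
  closure <- vapply(outcome, function(o) {
    switch(o,
      healed = min(21, max(7, round(stats::rnorm(1, cm[["healed"]],
                                                 cs[["healed"]])))),
      delayed = max(22, round(stats::rnorm(1, cm[["delayed"]],
                                           cs[["delayed"]]))),
      dehisced = min(21, max(6, round(stats::rnorm(1, cm[["dehisced"]],
                                                   cs[["dehisced"]])))))
  }, numeric(1))
  wound_area <- pmax(config$area_min,
                     stats::rlnorm(n_wounds, config$area_meanlog,
                                   config$area_sdlog))
  wound_sto2_offset <- stats::rnorm(n_wounds, 0, config$sto2_sd)
  rows <- list()
  img_i <- 0
  # Débridements recur every few days until closure, so wounds that stay
  # open longer (delayed healing) contribute more, and later, images.
  interval <- 15 / config$debridements_mean
  for (wi in seq_len(n_wounds)) {
    n_deb <- max(1, stats::rpois(1, closure[wi] / interval))
    days <- sort(unique(pmin(closure[wi] - 1, pmax(2, round(
      stats::runif(n_deb, 2, max(3, closure[wi] - 1)))))))
    n_deb <- length(days)
    for (di in seq_len(n_deb)) {
      img_i <- img_i + 1
      sto2 <- config$sto2_mean[[outcome[wi]]] + wound_sto2_offset[wi] +
        config$sto2_drift[[outcome[wi]]] * (di - 1) +
        stats::rnorm(1, 0, 0.02)
      art <- "none"; sev <- 0
      u <- stats::runif(1)
      rates <- config$artifact_rates
      if (u < rates[["glare"]]) {
        art <- "glare"; sev <- stats::runif(1, 0.06, 0.20)
      } else if (u < rates[["glare"]] + rates[["blur"]]) {
        art <- "blur"; sev <- stats::runif(1, 0.7, 1.0)
      } else if (u < sum(rates)) {
        art <- "blood"; sev <- stats::runif(1, 0.55, 0.9)
      }
      rows[[img_i]] <- data.frame(
        image_id = sprintf("img%04d", img_i),
        patient_id = sprintf("pat%03d", wound_patient[wi]),
        wound_id = sprintf("wnd%03d", wi),
        debridement_index = di,
        hospital = pat_hospital[wound_patient[wi]],
        wound_area_cm2 = round(wound_area[wi], 1),
        days_post_injury = days[di],
        age = pat_age[wound_patient[wi]],
        outcome = outcome[wi],
        true_sto2 = min(0.98, max(0.05, sto2)),
        artifact = art,
        artifact_severity = sev,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a synthetic cohort to disk
#'
#' Emits `images/*.png`, `masks/*.png`, a `cohort.csv` in the metadata-CSV
#' schema the pipeline reads (`image_id, path, roi_path, patient_id,
#' wound_id, debridement_index, hospital, wound_area_cm2, days_post_injury,
#' age, outcome` plus `true_sto2`), and a flat `config.yaml` echo.
#'
#' @param cohort a rendered [sample_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the metadata CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            length(cohort$images) > 0)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$metadata
  meta$path <- file.path("images", paste0(meta$image_id, ".png"))
  meta$roi_path <- file.path("masks", paste0(meta$image_id, ".png"))
  for (i in seq_len(nrow(meta))) {
    write_image(cohort$images[[i]], file.path(dir, meta$path[i]))
    write_atomic(file.path(dir, meta$roi_path[i]), function(tmp) {
      png::writePNG(cohort$masks[[i]] * 1, tmp)
    })
  }
  cols <- c("image_id", "path", "roi_path", "patient_id", "wound_id",
            "debridement_index", "hospital", "wound_area_cm2",
            "days_post_injury", "age", "outcome", "true_sto2")
  csv <- file.path(dir, "cohort.csv")
  write_atomic(csv, function(tmp) {
    utils::write.csv(meta[, cols], tmp, row.names = FALSE)
  })
  cfg <- cohort$config
  flat <- list(
    n_patients = cfg$n_patients,
    class_props = paste(sprintf("%s=%g", names(cfg$class_props),
                                cfg$class_props), collapse = ","),
    sto2_mean = paste(sprintf("%s=%g", names(cfg$sto2_mean),
                              cfg$sto2_mean), collapse = ","),
    image_size = cfg$image_size, noise_sd = cfg$noise_sd)
  write_atomic(file.path(dir, "config.yaml"), function(tmp) {
    writeLines(sprintf("%s: %s", names(flat), unlist(flat)), tmp)
  })
  invisible(csv)
}
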