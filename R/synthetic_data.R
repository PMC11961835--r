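#' Specification of a synthetic tumour phantom
#'
#' Phantoms emulate heterogeneous focal FDG uptake on a low background: a
#' base lesion sphere, optional hot "subclone" spheres inside it (the
#' mechanistic model of radioresistant subregions), additive Gaussian
#' noise, clipped at zero. The seed fully determines the output.
#'
#' @param shape Integer grid dimensions (voxels).
#' @param spacing Voxel spacing (mm).
#' @param background_suv Background SUV level.
#' @param lesion_radius_mm Radius of the base lesion sphere (mm); the
#'   lesion is centred in the grid and must fit inside it.
#' @param base_suv SUV of the base lesion.
#' @param subclones List of subclone spheres, each a list with `offset_mm`
#'   (length-3 offset of the subclone centre from the lesion centre),
#'   `radius_mm`, and `suv`.
#' @param noise_sd Additive Gaussian noise SD (SUV units).
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                         background_suv = 0.4, lesion_radius_mm = 10,
                         base_suv = 6, subclones = list(),
                         noise_sd = 0.3, seed = 1) {
  spec <- structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         background_suv = background_suv,
         lesion_radius_mm = lesion_radius_mm, base_suv = base_suv,
         subclones = subclones, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
  half_extent <- spec$shape * spec$spacing / 2
  if (any(lesion_radius_mm >= half_extent))
    stopf("lesion (radius %.1f mm) exceeds the grid (half-extent %s mm)",
          lesion_radius_mm, paste(format(half_extent), collapse = "x"))
  if (background_suv < 0 || base_suv <= 0)
    stopf("SUV levels must be positive")
  spec
}

# Physical coordinates (mm) of every voxel centre, n_voxels x 3.
voxel_coords <- function(shape, spacing) {
  idx <- arrayInd(seq_len(prod(shape)), shape)
  (idx - 1) %*% diag(spacing)
}

#' Generate a tumour phantom
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `pet_phantom`: `volume` ([suv_volume()]),
#'   `mask` ([roi_mask()], the true lesion support), `subclone_map`
#'   (integer array: 0 = base/background, i = subclone i), and the `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sd = 0, seed = 7))
#' ph$volume
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  coords <- voxel_coords(d, spec$spacing)
  centre <- (d - 1) * spec$spacing / 2
  r2 <- rowSums(sweep(coords, 2, centre, "-")^2)
  lesion <- r2 <= spec$lesion_radius_mm^2
  vals <- rep(spec$background_suv, prod(d))
  vals[lesion] <- spec$base_suv
  sub_map <- integer(prod(d))
  for (i in seq_along(spec$subclones)) {
    sc <- spec$subclones[[i]]
    sc_centre <- centre + sc$offset_mm
    if (sqrt(sum(sc$offset_mm^2)) + sc$radius_mm >
        spec$lesion_radius_mm + 1e-9)
      stopf("subclone %d extends outside the lesion", i)
    inside <- rowSums(sweep(coords, 2, sc_centre, "-")^2) <= sc$radius_mm^2
    vals[inside] <- sc$suv
    sub_map[inside] <- i
    lesion <- lesion | inside
  }
  if (spec$noise_sd > 0)
    vals <- vals + with_seed(spec$seed,
                             stats::rnorm(length(vals), sd = spec$noise_sd))
  vals <- pmax(vals, 0)
  vol <- suv_volume(array(vals, dim = d), spacing = spec$spacing,
                    scan_id = sprintf("phantom-%d", spec$seed),
                    timepoint = "week0")
  structure(list(volume = vol,
                 mask = roi_mask(array(lesion, dim = d), reference = vol),
                 subclone_map = array(sub_map, dim = d),
                 spec = spec),
            class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat(sprintf("<pet_phantom> seed %d, %d lesion voxel(s) (%.2f mL), %d subclone(s)\n",
              x$spec$seed, sum(x$mask$voxels),
              sum(x$mask$voxels) * prod(x$spec$spacing) / 1000,
              length(x$spec$subclones)))
  invisible(x)
}

#' Specification of a simulated mid-treatment response
#'
#' Emulates the typical mid-radiotherapy pattern: the metabolically active
#' volume shrinks, residual uptake declines, and radioresistant subclones
#' retain (part of) their excess uptake, driving persistent heterogeneity.
#'
#' @param volume_shrink_frac Fraction of the baseline lesion volume lost by
#'   week 3, in \[0, 1).
#' @param suv_decline_frac Fractional SUV decline of the base lesion, in
#'   \[0, 1).
#' @param subclone_persistence Per-subclone multiplier on the subclone's
#'   excess uptake over the declined base: 0 homogenises the subclone into
#'   the declined lesion, 1 keeps its full hot excess (radioresistance),
#'   values > 1 intensify it.
#' @param seed Integer seed (reserved for stochastic response components;
#'   the response itself is deterministic).
#' @return An object of class `response_spec`.
#' @export
response_spec <- function(volume_shrink_frac = 0.5, suv_decline_frac = 0.35,
                          subclone_persistence = numeric(), seed = 1) {
  if (volume_shrink_frac < 0 || volume_shrink_frac >= 1)
    stopf("volume_shrink_frac must be in [0, 1)")
  if (suv_decline_frac < 0 || suv_decline_frac >= 1)
    stopf("suv_decline_frac must be in [0, 1)")
  if (any(subclone_persistence < 0))
    stopf("subclone_persistence must be non-negative")
  structure(list(volume_shrink_frac = volume_shrink_frac,
                 suv_decline_frac = suv_decline_frac,
                 subclone_persistence = subclone_persistence,
                 seed = as.integer(seed)),
            class = "response_spec")
}

# Erode a foreground array to exactly `target` voxels by stripping
# 6-connected boundary shells; the final partial shell is removed
# outermost-first (largest distance to `centre_mm`), deterministically.
erode_to_count <- function(fg, target, spacing, centre_mm) {
  d <- dim(fg)
  shift <- function(a, ax, by) {
    out <- array(FALSE, dim = d)
    src <- dst <- lapply(d, seq_len)
    n <- d[ax]
    if (by == 1) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  while (sum(fg) > target) {
    interior <- fg
    for (ax in 1:3) for (by in c(1, -1)) {
      nb <- shift(fg, ax, by)
      # grid border counts as background
      interior <- interior & nb
    }
    shell <- which(fg & !interior)
    if (length(shell) == 0L) shell <- which(fg)
    n_over <- sum(fg) - target
    if (length(shell) <= n_over) {
      fg[shell] <- FALSE
    } else {
      co <- (arrayInd(shell, d) - 1) %*% diag(spacing)
      r <- rowSums(sweep(co, 2, centre_mm, "-")^2)
      drop_idx <- shell[order(-r, shell)[seq_len(n_over)]]
      fg[drop_idx] <- FALSE
    }
  }
  fg
}

#' Apply a simulated mid-treatment response to a baseline phantom
#'
#' The lesion support is eroded (boundary shells stripped outermost-first)
#' to `(1 - volume_shrink_frac)` of its baseline voxel count; surviving
#' base-lesion voxels decline by `suv_decline_frac`; subclone voxels become
#' `base * (1 - decline) + persistence * (excess over base)`, carrying the
#' baseline noise realisation through; eroded voxels revert to background;
#' voxels outside the lesion are untouched.
#'
#' @param baseline A [make_phantom()] result.
#' @param spec A [response_spec()].
#' @return A `pet_phantom` for the week-3 scan.
#' @export
apply_response <- function(baseline, spec) {
  stopifnot(inherits(baseline, "pet_phantom"), inherits(spec, "response_spec"))
  ps <- baseline$spec
  n_sub <- length(ps$subclones)
  pers <- rep_len(if (length(spec$subclone_persistence))
    spec$subclone_persistence else 0, max(n_sub, 1L))
  fg0 <- baseline$mask$voxels
  n0 <- sum(fg0)
  target <- round(n0 * (1 - spec$volume_shrink_frac))
  if (target < 1) stopf("response leaves no lesion voxel")
  centre <- (dim(fg0) - 1) * ps$spacing / 2
  fg3 <- erode_to_count(fg0, target, ps$spacing, centre)

  v0 <- baseline$volume$voxels
  expected0 <- array(ps$background_suv, dim = dim(v0))
  expected0[fg0] <- ps$base_suv
  for (i in seq_len(n_sub))
    expected0[baseline$subclone_map == i] <- ps$subclones[[i]]$suv
  noise <- v0 - pmax(expected0, 0)   # baseline noise realisation

  v3 <- v0
  keep_base <- fg3 & baseline$subclone_map == 0L
  v3[keep_base] <- ps$base_suv * (1 - spec$suv_decline_frac) +
    noise[keep_base]
  for (i in seq_len(n_sub)) {
    keep_sc <- fg3 & baseline$subclone_map == i
    v3[keep_sc] <- ps$base_suv * (1 - spec$suv_decline_frac) +
      pers[i] * (ps$subclones[[i]]$suv - ps$base_suv) + noise[keep_sc]
  }
  gone <- fg0 & !fg3
  v3[gone] <- ps$background_suv + noise[gone]
  v3 <- pmax(v3, 0)

  vol3 <- suv_volume(v3, spacing = ps$spacing,
                     scan_id = sprintf("%s-wk3", baseline$volume$scan_id),
                     timepoint = "week3")
  sub3 <- baseline$subclone_map
  sub3[!fg3] <- 0L
  structure(list(volume = vol3,
                 mask = roi_mask(fg3, reference = vol3),
                 subclone_map = sub3,
                 spec = ps, response = spec),
            class = "pet_phantom")
}

#' Specification of a simulated patient cohort
#'
#' Ties the imaging-response groups to time-to-recurrence outcomes. Each
#' patient is assigned a risk group; the group determines the distribution
#' of their simulated mid-treatment response (group 1 favourable volume
#' response, group 3 persistent hot subclones) and their exponential
#' monthly hazard of locoregional recurrence, with uniform administrative
#' censoring over the follow-up range. The default calibration reproduces
#' the qualitative cohort structure the pipeline targets (roughly 18%
#' 2-year recurrence overall with steep inter-group separation); it is a
#' calibration, not data.
#'
#' @param n_patients Cohort size (default 114).
#' @param group_fractions Length-3 mixing fractions over risk groups 1-3
#'   (must sum to 1).
#' @param group_s24 True 2-year (24-month) recurrence-free survival per
#'   group; converted to exponential hazards `-log(s24)/24`. Ignored when
#'   `group_hazards` is given.
#' @param group_hazards Optional explicit monthly hazards (length 3).
#' @param censor_range_months Administrative censoring window (months).
#' @param phantom Named list of phantom-generation ranges (see defaults).
#' @param response Per-group named lists of response ranges.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 114,
                        group_fractions = c(0.70, 0.20, 0.10),
                        group_s24 = c(0.93, 0.70, 0.17),
                        group_hazards = NULL,
                        censor_range_months = c(5, 88),
                        phantom = list(), response = list(), seed = 1) {
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stopf("group_fractions must sum to 1")
  hazards <- group_hazards %||% (-log(group_s24) / 24)
  if (any(hazards < 0)) stopf("hazards must be non-negative")
  ph <- utils::modifyList(list(
    shape = c(24L, 24L, 24L), spacing = c(2, 2, 2), background_suv = 0.4,
    lesion_radius_range = c(8, 13), base_suv_range = c(4, 8),
    subclone_rel_radius = c(0.35, 0.5), subclone_suv_mult = c(2.2, 2.8),
    noise_sd = 0.3), phantom)
  resp_default <- list(
    list(shrink = c(0.55, 0.75), decline = c(0.25, 0.40),
         persistence = c(0.25, 0.50)),
    list(shrink = c(0.15, 0.40), decline = c(0.25, 0.40),
         persistence = c(0.25, 0.50)),
    list(shrink = c(0.15, 0.40), decline = c(0.25, 0.40),
         persistence = c(1.00, 1.20)))
  rs <- if (length(response)) response else resp_default
  structure(list(n_patients = as.integer(n_patients),
                 group_fractions = group_fractions,
                 group_hazards = hazards,
                 censor_range_months = censor_range_months,
                 phantom = ph, response = rs, seed = as.integer(seed)),
            class = "cohort_spec")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Draw one patient's phantom + response parameters from the
# group-conditional distributions (RNG state assumed already seeded).
draw_patient_params <- function(spec, group) {
  ph <- spec$phantom
  r_les <- runif1(ph$lesion_radius_range)
  base <- runif1(ph$base_suv_range)
  r_sub <- runif1(ph$subclone_rel_radius) * r_les
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  mag <- (r_les - r_sub) * runif1(c(0.2, 0.7))
  sc_suv <- base * runif1(ph$subclone_suv_mult)
  rs <- spec$response[[group]]
  list(lesion_radius_mm = r_les, base_suv = base,
       subclone = list(offset_mm = dir * mag, radius_mm = r_sub,
                       suv = sc_suv),
       shrink = runif1(rs$shrink), decline = runif1(rs$decline),
       persistence = runif1(rs$persistence))
}

# Closed-form delta features implied by one patient's drawn parameters
# (feature-level simulation; the image route recomputes them from voxels).
analytic_deltas <- function(p) {
  b <- p$base_suv; e <- p$subclone$suv - b
  f_sub <- (p$subclone$radius_mm / p$lesion_radius_mm)^3
  b3 <- b * (1 - p$decline)
  max0 <- b + e; max3 <- max(b3 + p$persistence * e, b3)
  mean0 <- b + e * f_sub
  mean3 <- b3 + p$persistence * e * f_sub
  mtv_ratio <- 1 - p$shrink
  auc <- function(base_level, max_level, frac_hot) {
    if (max_level <= base_level * (1 + 1e-9)) return(1)
    base_level / max_level + (1 - base_level / max_level) * frac_hot
  }
  auc0 <- auc(b, max0, f_sub)
  auc3 <- auc(b3, max3, f_sub)
  c(d_suv_max = 100 * (max3 / max0 - 1),
    d_suv_mean = 100 * (mean3 / mean0 - 1),
    d_mtv = 100 * (mtv_ratio - 1),
    d_tlg = 100 * (mean3 * mtv_ratio / mean0 - 1),
    d_auc_csh = 100 * (auc3 / auc0 - 1))
}

#' Simulate a patient cohort with paired scans or pre-computed features
#'
#' Each patient receives a risk group, a baseline phantom, a
#' group-conditional mid-treatment response, and a time-to-recurrence
#' outcome (exponential recurrence time versus uniform administrative
#' censoring). With `images = TRUE` the paired phantoms are generated and
#' the five features extracted from the voxels at both timepoints; with
#' `images = FALSE` the delta features are computed in closed form from the
#' drawn parameters (fast path for outcome-level studies). Output is a
#' pure function of the spec (seed included).
#'
#' @param spec A [cohort_spec()].
#' @param images Generate voxel phantoms and extract features from them?
#' @param config [discretisation_config()] used when `images = TRUE`.
#' @return A list with `cohort` (patient records incl. `true_group`),
#'   `deltas` (per-patient percentage changes), `features` (per-scan
#'   feature rows; `images = TRUE` only), and the `spec`.
#' @export
simulate_cohort <- function(spec, images = FALSE,
                            config = discretisation_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  seeds <- derive_seeds(spec$seed, 2L * n)
  rows <- vector("list", n)
  feat_rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- with_seed(seeds[i], {
      g <- sample.int(3L, 1L, prob = spec$group_fractions)
      p <- draw_patient_params(spec, g)
      h <- spec$group_hazards[g]
      t_lrr <- if (h > 0) stats::rexp(1, rate = h) else Inf
      censor <- runif1(spec$censor_range_months)
      p16 <- sample(c("positive", "negative", "unknown"), 1L,
                    prob = c(0.48, 0.25, 0.27))
      list(group = g, params = p,
           followup = min(t_lrr, censor),
           event = as.integer(t_lrr <= censor),
           p16 = p16,
           tnm_stage = sample(c("II", "III", "IVa", "IVb", "IVc"), 1L,
                              prob = c(6, 18, 77, 10, 3)),
           t_stage = sample(c("T0", "T1", "T2", "T3", "T4"), 1L,
                            prob = c(3, 5, 39, 43, 24)),
           chemo = sample(c("Y", "N"), 1L, prob = c(0.85, 0.15)))
    })
    pid <- sprintf("P%03d", i)
    p <- rec$params
    if (images) {
      ph_spec <- phantom_spec(
        shape = spec$phantom$shape, spacing = spec$phantom$spacing,
        background_suv = spec$phantom$background_suv,
        lesion_radius_mm = p$lesion_radius_mm, base_suv = p$base_suv,
        subclones = list(p$subclone), noise_sd = spec$phantom$noise_sd,
        seed = seeds[n + i])
      base <- make_phantom(ph_spec)
      wk3 <- apply_response(base, response_spec(
        volume_shrink_frac = p$shrink, suv_decline_frac = p$decline,
        subclone_persistence = p$persistence, seed = seeds[n + i]))
      f0 <- extract_features(base$volume, base$mask, config)
      f3 <- extract_features(wk3$volume, wk3$mask, config)
      d <- delta_features(f0, f3, patient_id = pid)
      df0 <- as.data.frame(f0); df3 <- as.data.frame(f3)
      df0$patient_id <- pid; df3$patient_id <- pid
      feat_rows[[i]] <- rbind(df0, df3)
      dvec <- unlist(d[delta_feature_names])
    } else {
      dvec <- analytic_deltas(p)
    }
    rows[[i]] <- data.frame(
      patient_id = pid, p16 = rec$p16, tnm_stage = rec$tnm_stage,
      t_stage = rec$t_stage, chemo = rec$chemo,
      followup_months = rec$followup, lrr_event = rec$event,
      true_group = rec$group,
      d_suv_max = dvec[["d_suv_max"]], d_suv_mean = dvec[["d_suv_mean"]],
      d_mtv = dvec[["d_mtv"]], d_tlg = dvec[["d_tlg"]],
      d_auc_csh = dvec[["d_auc_csh"]], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  delta_cols <- c("patient_id", unname(delta_feature_names))
  list(cohort = tab[, c("patient_id", "p16", "tnm_stage", "t_stage",
                        "chemo", "followup_months", "lrr_event",
                        "true_group")],
       deltas = tab[, delta_cols],
       features = if (images) do.call(rbind, feat_rows) else NULL,
       spec = spec)
}
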