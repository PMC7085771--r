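#' Specify a synthetic cow cohort
#'
#' Bundles every knob of the generator: cohort size and subclinical-ketosis
#' prevalence (default 106/671 = 15.80%), the per-stream class effects on the
#' five behaviour streams (minutes per hour added to a sick animal's mean in
#' the post-partum week; the pre-partum week applies `pre_effect_factor` of
#' them), the per-feature class means/SDs (defaults from the 20-feature
#' schema, see [feature_schema()]), the missingness rates, and the series
#' length (168 = one week of hourly bins).
#'
#' Behaviour streams combine a diurnal sinusoid, an animal-level random
#' intercept, the class offset and hourly noise. The three activity states
#' (inactive / active / highly active) are drawn as a 60-minute three-part
#' composition (scaled gamma draws), so they sum to exactly 60 in every hour
#' by construction; lying and ruminating are independent streams clamped to
#' \[0, 60\].
#'
#' @param n_animals Cohort size (default 671).
#' @param prevalence Sick probability per animal (default 106/671).
#' @param series_length Hours per week (default 168).
#' @param stream_effects Named numeric vector: sick-minus-healthy mean offset
#'   (min/h, post-partum) for `lying`, `ruminating`, `inactive`, `active`,
#'   `highly_active`. The three activity offsets must sum to 0 to respect the
#'   60-minute budget.
#' @param pre_effect_factor Multiplier on `stream_effects` for the pre-partum
#'   week (default 0.6; the class contrast is weaker before calving).
#' @param animal_sd Animal-level random-intercept SD (min/h).
#' @param noise_sd Hourly noise SD for lying/ruminating (min/h).
#' @param concentration Gamma concentration of the activity composition
#'   (larger = less hourly variation).
#' @param feature_table Per-feature class means/SDs and bounds; defaults to
#'   [feature_schema()].
#' @param missing_rates Named rates for [apply_missingness()]; defaults to
#'   the schema's.
#' @param severity_link Within-animal correlation knob: SD of a per-sick-animal
#'   severity multiplier shared by stream offsets and feature shifts
#'   (0 = streams and features independent given the class, the default).
#' @param emit_bhb Also draw beta-hydroxybutyrate values for days 3/5/8 of
#'   lactation and derive labels from them via [label_from_bhb()]
#'   (default FALSE: labels are plain Bernoulli draws).
#' @param seed Default seed used by [generate_cohort()].
#' @return An object of class `cohort_spec` (a list).
#' @export
cohort_spec <- function(n_animals = 671,
                        prevalence = 106 / 671,
                        series_length = 168,
                        stream_effects = c(lying = 2.5, ruminating = -3.5,
                                           inactive = 2.5, active = -1.8,
                                           highly_active = -0.7),
                        pre_effect_factor = 0.6,
                        animal_sd = 4,
                        noise_sd = 7,
                        concentration = 25,
                        feature_table = feature_schema(),
                        missing_rates = NULL,
                        severity_link = 0,
                        emit_bhb = FALSE,
                        seed = 1L) {
  stopifnot(n_animals >= 1, prevalence > 0, prevalence < 1, series_length >= 1)
  stopifnot(setequal(names(stream_effects), .stream_names))
  stream_effects <- stream_effects[.stream_names]
  trio_sum <- sum(stream_effects[c("inactive", "active", "highly_active")])
  if (abs(trio_sum) > 1e-8) {
    stop("activity offsets must sum to 0 to keep the 60-minute budget; got ",
         signif(trio_sum, 3), call. = FALSE)
  }
  # stream base levels (min/h): lying ~13 h/day, ruminating ~8 h/day,
  # activity trio centred on (38, 15, 7) of the 60-minute budget
  base <- list(
    lying = list(mean = 33, amp = 8, phase = 3),
    ruminating = list(mean = 20, amp = 6, phase = 14),
    trio = c(inactive = 38, active = 15, highly_active = 7),
    trio_amp = c(inactive = 4, active = -3, highly_active = -1)
  )
  for (s in c("lying", "ruminating")) {
    hi <- base[[s]]$mean + base[[s]]$amp + max(stream_effects[[s]], 0)
    lo <- base[[s]]$mean - base[[s]]$amp + min(stream_effects[[s]], 0)
    if (hi > 60 || lo < 0) {
      stop("stream effect for '", s, "' pushes the mean outside [0, 60]",
           call. = FALSE)
    }
  }
  if (is.null(missing_rates)) {
    missing_rates <- setNames(feature_table$missing_rate, feature_table$feature)
  }
  structure(
    list(
      n_animals = as.integer(n_animals), prevalence = prevalence,
      series_length = as.integer(series_length),
      stream_effects = stream_effects, pre_effect_factor = pre_effect_factor,
      animal_sd = animal_sd, noise_sd = noise_sd,
      concentration = concentration, base = base,
      feature_table = feature_table, missing_rates = missing_rates,
      severity_link = severity_link, emit_bhb = emit_bhb,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# one truncated-Gaussian feature column; tails are redrawn, not clipped
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lower <- if (is.na(lower)) -Inf else lower
  upper <- if (is.na(upper)) Inf else upper
  out <- rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lower), upper)
}

# lying/ruminating stream matrix (n_animals x hours)
.gen_level_stream <- function(n, hours, base, offset, animal_eff, noise_sd) {
  diurnal <- base$amp * sin(2 * pi * ((seq_len(hours) - 1 + base$phase) %% 24) / 24)
  m <- matrix(rnorm(n * hours, 0, noise_sd), n, hours)
  m <- m + rep(diurnal, each = n) + base$mean + animal_eff + offset
  pmin(pmax(m, 0), 60)
}

# activity trio: per hour a 60-scaled gamma composition around class-specific
# target minutes; sums to exactly 60 by construction
.gen_trio <- function(n, hours, base, offsets, animal_eff, concentration) {
  diurnal <- sin(2 * pi * (((seq_len(hours) - 1) + 3) %% 24) / 24)
  out <- list(
    inactive = matrix(0, n, hours),
    active = matrix(0, n, hours),
    highly_active = matrix(0, n, hours)
  )
  targ <- array(0, c(n, hours, 3))
  for (k in 1:3) {
    s <- names(base$trio)[k]
    targ[, , k] <- base$trio[[s]] + offsets[, s] +
      rep(base$trio_amp[[s]] * diurnal, each = n) + animal_eff[, k]
  }
  targ <- pmax(targ, 0.5) # keep every component positive before renormalising
  tot <- targ[, , 1] + targ[, , 2] + targ[, , 3]
  g <- array(rgamma(n * hours * 3, shape = concentration * targ / rep(tot, 3)),
             c(n, hours, 3))
  gs <- g[, , 1] + g[, , 2] + g[, , 3]
  for (k in 1:3) out[[k]] <- 60 * g[, , k] / gs
  out
}

#' Generate a synthetic cohort
#'
#' Draws labels (Bernoulli at the spec prevalence, or from simulated BHB
#' values when `emit_bhb = TRUE`), the five hourly behaviour streams for the
#' pre- and post-partum weeks, and the 20-feature health table with
#' class-conditional truncated Gaussians (parity as a +/-1 Bernoulli). No
#' missingness is introduced here; see [apply_missingness()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to `spec$seed`); the same spec and seed
#'   give a byte-identical cohort.
#' @return An object of class `sck_cohort`: a list of tibbles `series_pre`,
#'   `series_post` (`animal_id`, `hour` 0-based, five stream columns),
#'   `features`, `labels`, optional `bhb`, plus the spec and seed.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  withr::with_seed(seed, .generate_cohort_impl(spec, seed))
}

.generate_cohort_impl <- function(spec, seed) {
  n <- spec$n_animals
  hours <- spec$series_length
  ids <- sprintf("cow_%04d", seq_len(n))

  if (spec$emit_bhb) {
    sick <- runif(n) < spec$prevalence
    bhb <- matrix(0, n, 3)
    # healthy: all three days below the 1.2 mmol/L cut; sick: one peak above
    bhb[!sick, ] <- .rtruncnorm(3 * sum(!sick), 0.68, 0.2, 0.05, 1.2)
    if (any(sick)) {
      ns <- sum(sick)
      bhb[sick, ] <- .rtruncnorm(3 * ns, 0.9, 0.25, 0.05, NA)
      peak <- sample.int(3, ns, replace = TRUE)
      bhb[cbind(which(sick), peak)] <- 1.2 + stats::rexp(ns, rate = 2.5) + 1e-3
    }
    bhb_tbl <- tibble::tibble(
      animal_id = ids,
      bhb_day3 = bhb[, 1], bhb_day5 = bhb[, 2], bhb_day8 = bhb[, 3]
    )
    labels <- vapply(seq_len(n), function(i) {
      label_from_bhb(bhb[i, 1], bhb[i, 2], bhb[i, 3])
    }, character(1))
  } else {
    bhb_tbl <- NULL
    labels <- ifelse(runif(n) < spec$prevalence, "sick", "healthy")
  }
  is_sick <- labels == "sick"

  # shared per-animal severity multiplier (correlation knob)
  severity <- rep(1, n)
  if (spec$severity_link > 0 && any(is_sick)) {
    severity[is_sick] <- pmax(rnorm(sum(is_sick), 1, spec$severity_link), 0.2)
  }

  make_frame <- function(effect_factor) {
    eff <- function(stream) {
      spec$stream_effects[[stream]] * effect_factor * severity * is_sick
    }
    lying <- .gen_level_stream(n, hours, spec$base$lying, eff("lying"),
                               rnorm(n, 0, spec$animal_sd), spec$noise_sd)
    rumin <- .gen_level_stream(n, hours, spec$base$ruminating, eff("ruminating"),
                               rnorm(n, 0, spec$animal_sd), spec$noise_sd)
    offs <- cbind(inactive = eff("inactive"), active = eff("active"),
                  highly_active = eff("highly_active"))
    a_eff <- rnorm(n, 0, spec$animal_sd * 0.75)
    trio <- .gen_trio(n, hours, spec$base, offs,
                      cbind(a_eff, -0.7 * a_eff, -0.3 * a_eff),
                      spec$concentration)
    tibble::tibble(
      animal_id = rep(ids, each = hours),
      hour = rep(seq_len(hours) - 1L, n),
      lying = as.vector(t(lying)),
      ruminating = as.vector(t(rumin)),
      inactive = as.vector(t(trio$inactive)),
      active = as.vector(t(trio$active)),
      highly_active = as.vector(t(trio$highly_active))
    )
  }
  series_pre <- make_frame(spec$pre_effect_factor)
  series_post <- make_frame(1)

  ft <- spec$feature_table
  feats <- purrr::map(seq_len(nrow(ft)), function(r) {
    f <- ft[r, ]
    mu <- ifelse(is_sick,
                 f$mean_healthy + severity * (f$mean_sick - f$mean_healthy),
                 f$mean_healthy)
    sdv <- ifelse(is_sick, f$sd_sick, f$sd_healthy)
    if (f$feature == "parity") {
      p_multi <- pmin(pmax((1 + mu) / 2, 0), 1)
      ifelse(runif(n) < p_multi, 1, -1)
    } else {
      .rtruncnorm(n, mu, sdv, f$lower, f$upper)
    }
  })
  features <- tibble::as_tibble(setNames(feats, ft$feature))
  features <- dplyr::bind_cols(tibble::tibble(animal_id = ids), features)

  structure(
    list(
      series_pre = series_pre, series_post = series_post,
      features = features,
      labels = tibble::tibble(animal_id = ids, label = labels),
      bhb = bhb_tbl, spec = spec, seed = seed
    ),
    class = "sck_cohort"
  )
}

#' @export
print.sck_cohort <- function(x, ...) {
  counts <- table(factor(x$labels$label, .classes))
  cat("<sck_cohort> ", nrow(x$labels), " animals (",
      counts[["healthy"]], " healthy / ", counts[["sick"]], " sick), ",
      x$spec$series_length, " hourly bins per week, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Mask features missing-completely-at-random
#'
#' Applies MCAR masking at the given per-feature rates, with the structural
#' couplings of on-farm recording: the BCS/BFT measurements of the same visit
#' (`bcs_8w`/`bft_8w`, `bcs_3w`/`bft_3w`, `bcs_d0`/`bft_d0`) are masked
#' jointly (one missed visit loses both), and the nine location features come
#' from a single source and are masked as a block.
#'
#' @param cohort An `sck_cohort` (or a bare feature data frame).
#' @param rates Named numeric vector of per-feature rates in \[0, 1\];
#'   defaults to the cohort spec's (the schema's Table-like defaults). Joint
#'   groups use the rate of their first member.
#' @param seed Integer seed.
#' @return The cohort (or feature table) with `NA`s introduced.
#' @export
apply_missingness <- function(cohort, rates = NULL, seed = 1L) {
  is_cohort <- inherits(cohort, "sck_cohort")
  features <- if (is_cohort) cohort$features else tibble::as_tibble(cohort)
  if (is.null(rates)) {
    rates <- if (is_cohort) cohort$spec$missing_rates else
      setNames(feature_schema()$missing_rate, feature_schema()$feature)
  }
  present <- intersect(names(rates), names(features))
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  n <- nrow(features)
  loc_block <- intersect(feature_schema()$feature[feature_schema()$location],
                         present)
  visit_pairs <- list(c("bcs_8w", "bft_8w"), c("bcs_3w", "bft_3w"),
                      c("bcs_d0", "bft_d0"))
  grouped <- c(loc_block, unlist(visit_pairs))
  features <- withr::with_seed(seed, {
    for (pair in visit_pairs) {
      pair <- intersect(pair, present)
      if (length(pair) == 0) next
      mask <- runif(n) < rates[[pair[1]]]
      for (f in pair) features[[f]][mask] <- NA_real_
    }
    if (length(loc_block) > 0) {
      mask <- runif(n) < rates[[loc_block[1]]]
      for (f in loc_block) features[[f]][mask] <- NA_real_
    }
    for (f in setdiff(present, grouped)) {
      if (rates[[f]] > 0) {
        mask <- runif(n) < rates[[f]]
        features[[f]][mask] <- NA_real_
      }
    }
    features
  })
  if (is_cohort) {
    cohort$features <- features
    cohort
  } else {
    features
  }
}

#' Label an animal from its BHB measurements
#'
#' An animal is `"sick"` (subclinical ketosis) if any available
#' beta-hydroxybutyrate value from days 3, 5 or 8 of lactation is strictly
#' above 1.2 mmol/L; exactly 1.2 is healthy. At least one value must be
#' non-missing.
#'
#' @param bhb_day3,bhb_day5,bhb_day8 BHB concentrations in mmol/L (`NA` =
#'   missing). Alternatively `bhb_day3` may be a data frame with columns
#'   `bhb_day3`, `bhb_day5`, `bhb_day8`, in which case a `label` column is
#'   appended and the tibble returned.
#' @param cutoff Diagnostic threshold in mmol/L (default 1.2).
#' @return A label, or the input tibble with a `label` column.
#' @export
label_from_bhb <- function(bhb_day3, bhb_day5 = NA, bhb_day8 = NA,
                           cutoff = 1.2) {
  if (is.data.frame(bhb_day3)) {
    df <- bhb_day3
    stopifnot(all(c("bhb_day3", "bhb_day5", "bhb_day8") %in% names(df)))
    df$label <- vapply(seq_len(nrow(df)), function(i) {
      label_from_bhb(df$bhb_day3[i], df$bhb_day5[i], df$bhb_day8[i], cutoff)
    }, character(1))
    return(tibble::as_tibble(df))
  }
  v <- c(bhb_day3, bhb_day5, bhb_day8)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("all BHB values missing", call. = FALSE)
  if (any(v < 0)) stop("BHB concentrations cannot be negative", call. = FALSE)
  if (any(v > cutoff)) "sick" else "healthy"
}
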