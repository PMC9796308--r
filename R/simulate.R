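#' Generative parameters for the task-switching simulator
#'
#' Defines the ground-truth data-generating process for synthetic sessions.
#' A trial's expected RT (ms) is
#' \deqn{baseRt - spatialAdvantage \cdot 1[spatial] + slope \cdot nComp +
#'       biCost \cdot 1[ABA] + crsCost \cdot 1[CRS+] + intercept_i}
#' with ex-Gaussian residual noise (Normal sd `sigma` plus Exponential mean
#' `tau`), and the error probability is
#' `base_error_rate + error_slope * nComp`, clipped to \[0, 1\].
#' Participant heterogeneity is normal on the intercept and on the three
#' effect parameters.
#'
#' Group effects are injected on the effect parameters of the anti group:
#' a standardized difference `group_d[index]` shifts the anti-group mean of
#' the corresponding parameter by `group_d * index_sd` (for the congruency
#' slope, by `group_d * index_sd / 10`, since the linear contrast scales
#' the slope by 10). `index_sd` holds the assumed between-participant SDs
#' of the three RT indices. The FWI manipulation effect is a standardized
#' shift `fwi_group_d` between the groups' questionnaire scores.
#'
#' @param base_rt Baseline RT in ms for object tasks.
#' @param spatial_advantage RT advantage (ms) of spatial over object tasks.
#' @param congruency_slope RT cost in ms per competitor S-R set.
#' @param bi_cost Backward-inhibition cost (ms) on ABA trials.
#' @param crs_cost Competitor-rule-suppression cost (ms) on CRS+ trials.
#' @param intercept_sd Between-participant SD (ms) of the intercept.
#' @param congruency_slope_sd,bi_cost_sd,crs_cost_sd Between-participant
#'   SDs of the effect parameters (ms).
#' @param sigma,tau Ex-Gaussian residual parameters (ms).
#' @param base_error_rate Error probability on 0-competitor trials.
#' @param error_slope Error-probability increment per competitor.
#' @param group_d Named numeric, standardized shifts (anti minus pro) on
#'   the indices `lin_cong`, `bi`, `crs`.
#' @param fwi_group_d Standardized shift (pro minus anti) of the free-will
#'   inventory score.
#' @param index_sd Assumed between-participant SDs of the RT indices used
#'   to convert `group_d` into parameter shifts.
#' @return An object of class `gen_params`.
#' @export
gen_params <- function(base_rt = 900, spatial_advantage = 50,
                       congruency_slope = 34, bi_cost = 25, crs_cost = 35,
                       intercept_sd = 100, congruency_slope_sd = 27,
                       bi_cost_sd = 50, crs_cost_sd = 80,
                       sigma = 50, tau = 100,
                       base_error_rate = 0.05, error_slope = 0.02,
                       group_d = c(lin_cong = 0, bi = 0, crs = 0),
                       fwi_group_d = 0.70,
                       index_sd = c(lin_cong = 283, bi = 53, crs = 86)) {
  gd <- c(lin_cong = 0, bi = 0, crs = 0)
  gd[names(group_d)] <- group_d
  isd <- c(lin_cong = 283, bi = 53, crs = 86)
  isd[names(index_sd)] <- index_sd
  p <- list(base_rt = base_rt, spatial_advantage = spatial_advantage,
            congruency_slope = congruency_slope, bi_cost = bi_cost,
            crs_cost = crs_cost, intercept_sd = intercept_sd,
            congruency_slope_sd = congruency_slope_sd,
            bi_cost_sd = bi_cost_sd, crs_cost_sd = crs_cost_sd,
            sigma = sigma, tau = tau,
            base_error_rate = base_error_rate, error_slope = error_slope,
            group_d = gd, fwi_group_d = fwi_group_d, index_sd = isd)
  validate_gen_params(p)
  structure(p, class = "gen_params")
}

validate_gen_params <- function(p) {
  stopifnot(is.numeric(p$base_rt), is.numeric(p$sigma), is.numeric(p$tau))
  if (p$sigma < 0 || p$tau < 0 || p$intercept_sd < 0 ||
      p$congruency_slope_sd < 0 || p$bi_cost_sd < 0 || p$crs_cost_sd < 0) {
    stop("parameter validation: sd/tau parameters must be >= 0",
         call. = FALSE)
  }
  if (p$base_error_rate < 0 || p$base_error_rate > 1) {
    stop("parameter validation: base_error_rate must be in [0, 1]",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.gen_params <- function(x, ...) {
  cat("Generative parameters (RT in ms):\n")
  cat(sprintf("  base %g, spatial advantage %g, congruency slope %g/comp, BI cost %g, CRS cost %g\n",
              x$base_rt, x$spatial_advantage, x$congruency_slope,
              x$bi_cost, x$crs_cost))
  cat(sprintf("  participant SDs: intercept %g, slope %g, BI %g, CRS %g; ex-Gaussian sigma %g, tau %g\n",
              x$intercept_sd, x$congruency_slope_sd, x$bi_cost_sd,
              x$crs_cost_sd, x$sigma, x$tau))
  cat(sprintf("  errors: base %.3f + %.3f/competitor\n",
              x$base_error_rate, x$error_slope))
  cat(sprintf("  group d (anti - pro): lin_cong %.2f, bi %.2f, crs %.2f; FWI d %.2f\n",
              x$group_d[["lin_cong"]], x$group_d[["bi"]],
              x$group_d[["crs"]], x$fwi_group_d))
  invisible(x)
}

# Effect-parameter means for one group. The anti group's parameters are
# shifted by group_d expressed on the index scale.
group_effect_means <- function(params, group) {
  shift <- if (identical(group, "anti")) 1 else 0
  list(
    slope = params$congruency_slope +
      shift * params$group_d[["lin_cong"]] * params$index_sd[["lin_cong"]] / 10,
    bi = params$bi_cost + shift * params$group_d[["bi"]] * params$index_sd[["bi"]],
    crs = params$crs_cost + shift * params$group_d[["crs"]] * params$index_sd[["crs"]]
  )
}

#' Simulate one trial's RT and accuracy
#'
#' Exposes the trial-level generative model directly: deterministic linear
#' RT structure plus ex-Gaussian noise, and a competitor-dependent error
#' probability.
#'
#' @param n_competitors Integer 0..3.
#' @param bi_label `"ABA"`, `"CBA"` or `"unclassified"`.
#' @param crs_label `"CRSplus"`, `"CRSminus"` or `"ineligible"`.
#' @param task Task dimension of the trial.
#' @param params A `gen_params` object.
#' @param participant_intercept Participant intercept deviation (ms).
#' @param seed Optional seed.
#' @return List with elements `rt` (ms) and `correct` (logical).
#' @export
simulate_trial <- function(n_competitors, bi_label = "CBA",
                           crs_label = "ineligible", task = "colour",
                           params = gen_params(),
                           participant_intercept = 0, seed = NULL) {
  if (n_competitors < 0 || n_competitors > 3) {
    stop("n_competitors must be in 0..3", call. = FALSE)
  }
  mu <- params$base_rt -
    params$spatial_advantage * (task %in% SPATIAL_TASKS) +
    params$congruency_slope * n_competitors +
    params$bi_cost * (bi_label == "ABA") +
    params$crs_cost * (crs_label == "CRSplus") +
    participant_intercept
  if (mu <= 0) {
    stop("parameter validation: non-positive mean RT", call. = FALSE)
  }
  p_err <- clip01(params$base_error_rate + params$error_slope * n_competitors)
  with_seed(seed, {
    rt <- mu +
      (if (params$sigma > 0) stats::rnorm(1, 0, params$sigma) else 0) +
      (if (params$tau > 0) stats::rexp(1, 1 / params$tau) else 0)
    list(rt = rt, correct = stats::runif(1) >= p_err)
  })
}

#' Simulate a full session for one participant
#'
#' Generates a 100%-switch task sequence, draws stimuli uniformly among the
#' 16 feature combinations, derives the trial features (competitor count,
#' ABA/CBA, CRS condition) by running the classifier on the generated
#' sequence, and only then generates RTs and errors from the generative
#' model, so that the ground-truth effects act on exactly the features the
#' analysis pipeline later recovers.
#'
#' @param participant_id Identifier.
#' @param group `"pro"` or `"anti"`.
#' @param mapping A `response_mapping` (or integer mapping id).
#' @param params A `gen_params` object.
#' @param n_blocks,trials_per_block Session structure (default 7 x 64).
#' @param seed Optional seed.
#' @return Data frame of trials with columns `participant`, `group`,
#'   `mapping`, `block`, `trial`, `task`, the four feature columns,
#'   `correct_key`, `response_key`, `correct`, `rt_ms`.
#' @export
simulate_participant <- function(participant_id, group = "pro",
                                 mapping = response_mapping(1),
                                 params = gen_params(),
                                 n_blocks = 7, trials_per_block = 64,
                                 seed = NULL) {
  if (is.numeric(mapping)) mapping <- response_mapping(mapping)
  if (!group %in% c("pro", "anti")) {
    stop("group must be 'pro' or 'anti'", call. = FALSE)
  }
  validate_gen_params(params)
  if (params$base_rt - params$spatial_advantage <= 0) {
    stop("parameter validation: non-positive mean RT", call. = FALSE)
  }
  with_seed(seed, {
    n <- n_blocks * trials_per_block
    tasks <- generate_task_sequence(n_blocks, trials_per_block, 4)
    stim <- stimulus_set()[sample.int(16, n, replace = TRUE), ]
    rownames(stim) <- NULL
    trials <- data.frame(
      participant = rep(participant_id, n),
      group = rep(group, n),
      mapping = rep(mapping$id, n),
      block = rep(seq_len(n_blocks), each = trials_per_block),
      trial = rep(seq_len(trials_per_block), times = n_blocks),
      task = tasks,
      stim,
      stringsAsFactors = FALSE
    )
    feat <- classify_sequence(trials, mapping)

    eff <- group_effect_means(params, group)
    intercept <- stats::rnorm(1, 0, params$intercept_sd)
    slope_i <- stats::rnorm(1, eff$slope, params$congruency_slope_sd)
    bi_i <- stats::rnorm(1, eff$bi, params$bi_cost_sd)
    crs_i <- stats::rnorm(1, eff$crs, params$crs_cost_sd)

    mu <- params$base_rt -
      params$spatial_advantage * (trials$task %in% SPATIAL_TASKS) +
      slope_i * feat$n_competitors +
      bi_i * (feat$bi_label == "ABA") +
      crs_i * (feat$crs_label == "CRSplus") +
      intercept
    rt <- mu
    if (params$sigma > 0) rt <- rt + stats::rnorm(n, 0, params$sigma)
    if (params$tau > 0) rt <- rt + stats::rexp(n, 1 / params$tau)
    rt <- pmax(rt, 1)

    p_err <- clip01(params$base_error_rate +
                      params$error_slope * feat$n_competitors)
    correct <- stats::runif(n) >= p_err
    trials$correct_key <- feat$correct_key
    trials$response_key <- ifelse(correct, feat$correct_key,
                                  3L - feat$correct_key)
    trials$correct <- correct
    trials$rt_ms <- rt
    trials
  })
}

#' Simulate a two-group experiment
#'
#' Balanced pro and anti free-will groups with the eight response mappings
#' counterbalanced within each group, plus questionnaire item responses
#' (free-will inventory, fatigue, locus of control) per participant, with
#' the FWI manipulation effect `fwi_group_d` applied between groups.
#'
#' @param n_per_group Participants per group.
#' @param params A `gen_params` object.
#' @param seed Optional seed.
#' @param n_blocks,trials_per_block Session structure.
#' @return List with `trials` (long trial table) and `questionnaires`
#'   (one row of item responses per participant).
#' @export
simulate_group <- function(n_per_group, params = gen_params(), seed = NULL,
                           n_blocks = 7, trials_per_block = 64) {
  stopifnot(n_per_group >= 1)
  with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(2 * n_per_group))
    groups <- rep(c("pro", "anti"), each = n_per_group)
    mappings <- c(rep_len(1:8, n_per_group), rep_len(1:8, n_per_group))
    trials <- do.call(rbind, lapply(seq_along(ids), function(i) {
      simulate_participant(ids[i], groups[i], mappings[i], params,
                           n_blocks, trials_per_block)
    }))
    q <- simulate_questionnaires(ids, groups, params)
    list(trials = trials, questionnaires = q)
  })
}

# Item-level questionnaire generator. Latent-normal traits are mapped to
# 1..7 ratings by rounding and clamping; the FWI group shift is applied on
# the latent scale, calibrated (see the methods vignette) so that the
# composite-score standardized difference approximates fwi_group_d.
simulate_questionnaires <- function(ids, groups, params) {
  n <- length(ids)
  # composite SD implied by the item model: sqrt(1.2^2 + 0.8^2/5 + 1/12)
  comp_sd <- sqrt(1.2^2 + 0.8^2 / 5 + 1 / 12)
  shift <- ifelse(groups == "pro", 0.5, -0.5) * params$fwi_group_d * comp_sd
  theta <- stats::rnorm(n)
  fwi <- sapply(1:5, function(j) {
    clamp_rating(round(4.2 + 1.2 * theta + shift + stats::rnorm(n, 0, 0.8)))
  })
  colnames(fwi) <- paste0("fwi_", 1:5)

  fat_trait <- stats::rnorm(n)
  tired <- clamp_rating(round(3.5 + fat_trait + stats::rnorm(n, 0, 0.9)))
  bored <- clamp_rating(round(3.5 + fat_trait + stats::rnorm(n, 0, 0.9)))
  alert <- clamp_rating(round(4.5 - fat_trait + stats::rnorm(n, 0, 0.9)))
  energetic <- clamp_rating(round(4.5 - fat_trait + stats::rnorm(n, 0, 0.9)))

  loc_trait <- stats::rnorm(n)
  loc <- sapply(1:23, function(j) {
    as.integer(stats::runif(n) < stats::plogis(-0.35 + 0.8 * loc_trait))
  })
  colnames(loc) <- paste0("loc_", 1:23)

  data.frame(participant = ids, group = groups, fwi,
             fatigue_tired = tired, fatigue_bored = bored,
             fatigue_alert = alert, fatigue_energetic = energetic,
             loc, stringsAsFactors = FALSE)
}

clamp_rating <- function(x) pmin(pmax(x, 1), 7)
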