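# Analysis registry: model specifications for each contrast family.
#
# Each entry names the response, the fixed-effect design, the random
# hierarchy (always grouped within subject, with electrodes or
# electrode pairs nested where the analysis is electrode-level), the
# response transform, and the exclusion rules applied before fitting.

analysis_registry <- function() {
  list(
    behavior_reward = list(
      response = "turnaround_distance",
      fixed = ~ last_dot_size_small,
      random = "subject",
      transform = "scale",
      required = c("turnaround_distance", "last_dot_size", "subject"),
      exclusions = function(d) {
        if ("conflict" %in% names(d)) d <- dplyr::filter(d, .data$conflict)
        if ("n_turnarounds" %in% names(d)) {
          d <- dplyr::filter(d, .data$n_turnarounds > 0)
        }
        dplyr::filter(d, !is.na(.data$turnaround_distance))
      },
      prepare = function(d) {
        d$last_dot_size_small <- as.numeric(d$last_dot_size == "small")
        d
      },
      description = "turnaround distance ~ last-reward size, random subject"
    ),
    theta_approach_avoid = list(
      response = "theta",
      fixed = ~ approach,
      random = c("subject", "electrode"),
      transform = "none",
      required = c("theta", "period", "subject", "electrode"),
      exclusions = function(d) {
        if ("conflict" %in% names(d)) d <- dplyr::filter(d, .data$conflict)
        if ("attack" %in% names(d)) d <- dplyr::filter(d, !.data$attack)
        if ("dots_collected" %in% names(d)) {
          d <- dplyr::filter(d, .data$dots_collected > 0)
        }
        d
      },
      prepare = function(d) {
        d$approach <- as.numeric(d$period == "approach")
        d
      },
      description = "theta power ~ approach vs avoidance, random subject/electrode"
    ),
    theta_approach_return_cf = list(
      response = "theta",
      fixed = ~ approach,
      random = c("subject", "electrode"),
      transform = "none",
      required = c("theta", "period", "subject", "electrode"),
      exclusions = function(d) {
        if ("conflict" %in% names(d)) d <- dplyr::filter(d, !.data$conflict)
        if ("dots_collected" %in% names(d)) {
          d <- dplyr::filter(d, .data$dots_collected > 0)
        }
        d
      },
      prepare = function(d) {
        d$approach <- as.numeric(d$period == "approach")
        d
      },
      description = "conflict-free theta ~ approach vs return, random subject/electrode"
    ),
    coherence_partner_region = list(
      response = "coherence",
      fixed = ~ partner_region,
      random = c("subject", "electrode"),
      transform = "log",
      required = c("coherence", "partner_region", "subject", "electrode"),
      exclusions = identity,
      prepare = function(d) {
        d$partner_region <- factor(d$partner_region)
        d
      },
      description = "logged coherence ~ partner region (factor), random subject/electrode"
    ),
    coherence_time = list(
      response = "coherence",
      fixed = ~ time,
      random = c("subject", "electrode"),
      transform = "log_scale",
      required = c("coherence", "time", "subject", "electrode"),
      exclusions = identity,
      prepare = function(d) { d$time <- as.numeric(scale(d$time)); d },
      description = "logged, scaled coherence ~ time, random subject/electrode-pair"
    ),
    granger_direction = list(
      response = "net_gc",
      fixed = ~ 1,
      random = c("subject", "electrode"),
      transform = "scale_nocenter",
      required = c("net_gc", "subject", "electrode"),
      exclusions = identity,
      prepare = identity,
      description = "intercept-only net Granger, scaled not centered"
    ),
    ccf_direction = list(
      response = "best_lag",
      fixed = ~ 1,
      random = c("subject", "electrode"),
      transform = "scale_nocenter",
      required = c("best_lag", "subject", "electrode"),
      exclusions = identity,
      prepare = identity,
      description = "intercept-only best cross-correlation lag, scaled not centered"
    ),
    synchrony_time = list(
      response = "synchrony",
      fixed = ~ approach_time,
      random = c("subject", "electrode"),
      transform = "scale",
      required = c("synchrony", "approach_time", "subject", "electrode"),
      exclusions = identity,
      prepare = function(d) {
        # approach times are logged then scaled
        d$approach_time <- as.numeric(scale(log(d$approach_time)))
        d
      },
      description = "scaled synchrony ~ logged, scaled approach time"
    ),
    hfa_attack = list(
      response = "hfa",
      fixed = ~ time * chase,
      random = c("subject", "electrode"),
      transform = "scale",
      required = c("hfa", "time", "attack_type", "subject", "electrode"),
      exclusions = function(d) {
        if ("hemisphere" %in% names(d)) {
          d <- dplyr::filter(d, .data$hemisphere == "R")
        }
        dplyr::filter(d, !is.na(.data$attack_type))
      },
      prepare = function(d) {
        d$chase <- as.numeric(d$attack_type == "chase")
        d$time <- as.numeric(scale(d$time))
        d
      },
      description = "right-MFG HFA ~ time x attack type (Chase vs Strike)"
    )
  )
}

#' Available hierarchical analyses
#'
#' @return Tibble listing each analysis id with its model description.
#' @export
list_analyses <- function() {
  reg <- analysis_registry()
  tibble(analysis_id = names(reg),
         description = map_chr(reg, "description"))
}

apply_transform <- function(y, transform) {
  switch(transform,
         none = y,
         scale = as.numeric(scale(y)),
         log = {
           if (any(y <= 0)) stop_bad("log transform requires positive response")
           log(y)
         },
         log_scale = {
           if (any(y <= 0)) stop_bad("log transform requires positive response")
           as.numeric(scale(log(y)))
         },
         scale_nocenter = y / sd(y),
         stop_bad("unknown transform `%s`", transform))
}

#' Build a hierarchical model specification from the analysis registry
#'
#' Selects the registry row for `analysis_id`, applies its exclusion
#' rules and response transform to the data, and constructs the
#' fixed-effect design matrix and random-effect grouping indices.
#'
#' @param analysis_id One of the ids in [list_analyses()].
#' @param data Tidy data with the columns the analysis requires
#'   (response, predictors, `subject`, and `electrode` for
#'   electrode-level analyses; for pair-level analyses the first
#'   electrode of the pair plays the electrode role).
#' @return A `model_spec`: the filtered/transformed data, design matrix
#'   `X`, random grouping labels, priors, and bookkeeping.
#' @export
build_model <- function(analysis_id, data) {
  reg <- analysis_registry()
  if (!analysis_id %in% names(reg)) {
    stop_bad("unknown analysis_id `%s`; see list_analyses()", analysis_id)
  }
  entry <- reg[[analysis_id]]
  data <- as_tibble(data)
  missing_cols <- setdiff(entry$required, names(data))
  if (length(missing_cols)) {
    stop_bad("data lacks required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  d <- entry$exclusions(data)
  if (nrow(d) == 0) stop_bad("no rows left after exclusions")
  d <- entry$prepare(d)
  d$.y <- apply_transform(d[[entry$response]], entry$transform)
  X <- stats::model.matrix(entry$fixed, d)
  groups <- list(subject = as.character(d$subject))
  if ("electrode" %in% entry$random) {
    # nest electrodes within subject
    groups$electrode <- paste(d$subject, d$electrode, sep = ":")
  }
  structure(
    list(analysis_id = analysis_id, response = entry$response,
         transform = entry$transform, data = d, X = X, groups = groups,
         description = entry$description,
         priors = list(intercept_sd = 5, coef_sd = 2, ranef_rate = 1,
                       sigma_rate = 1)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %s\n  n = %d, fixed: %s, random: %s\n",
              x$analysis_id, x$description, nrow(x$X),
              paste(colnames(x$X), collapse = " + "),
              paste(names(x$groups), collapse = "/")))
  invisible(x)
}
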