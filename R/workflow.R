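#' Cluster manual alerts into telemonitoring actions
#'
#' All manually routed alerts generated by one user on one day are handled
#' together in a single telemonitoring action by the e-nurse. Alerts
#' triggered on a Saturday or Sunday are consolidated into the following
#' Monday's action, since alerts are only reviewed during office hours; no
#' action ever carries a weekend processing date.
#'
#' @param manual_alerts Alert tibble, all rows routed `"manual"`; any
#'   auto-routed row is a contract violation.
#' @return Tibble of unclassified actions: `action_id`, `user_id`,
#'   `processing_date`, `member_alert_ids` (semicolon-joined), `n_alerts`,
#'   `max_exceedance` (largest simple-alert threshold exceedance among
#'   members, 0 if none — the severity covariate for classification).
#'   Every manual alert belongs to exactly one action.
#' @export
cluster_actions <- function(manual_alerts) {
  if (nrow(manual_alerts) > 0 && any(manual_alerts$routing != "manual"))
    contract_error("cluster_actions received a non-manual alert")
  if (nrow(manual_alerts) == 0) {
    return(tibble::tibble(
      action_id = character(), user_id = character(),
      processing_date = as.Date(character()), member_alert_ids = character(),
      n_alerts = integer(), max_exceedance = numeric()))
  }
  wd <- iso_weekday(manual_alerts$trigger_date)
  shift <- ifelse(wd == 6, 2L, ifelse(wd == 7, 1L, 0L))
  manual_alerts$processing_date <- manual_alerts$trigger_date + shift
  acts <- dplyr::summarise(
    dplyr::group_by(manual_alerts, .data$user_id, .data$processing_date),
    member_alert_ids = paste(sort(.data$alert_id), collapse = ";"),
    n_alerts = dplyr::n(),
    max_exceedance = max(c(0, .data$exceedance), na.rm = TRUE),
    .groups = "drop")
  acts <- dplyr::arrange(acts, .data$user_id, .data$processing_date)
  tibble::add_column(
    acts,
    action_id = sprintf("T:%s:%s", acts$user_id, format(acts$processing_date)),
    .before = 1)
}

#' Stochastic e-nurse action-classification model
#'
#' The real administrative-versus-clinical decision is a human judgement;
#' this model reproduces its marginals. An action is administrative with
#' probability `p_administrative` and otherwise clinical with one of four
#' subtypes (telephone or secure message, each with or without a treatment
#' adjustment). A severity covariate is on by default: the action's maximal
#' simple-alert exceedance shifts the clinical probability on the logistic
#' scale by `magnitude_slope` per mmHg, centred so the marginal
#' administrative share stays exactly at `p_administrative`. Higher-valued
#' surviving alerts in threshold scenarios therefore skew clinical, as
#' observed processing does.
#'
#' @param p_administrative Marginal probability an action is administrative
#'   (default 0.77).
#' @param clinical_subtype_probs Named probabilities over
#'   `phone_no_adjust`, `phone_adjust`, `message_no_adjust`,
#'   `message_adjust`; must sum to 1 (defaults 0.40/0.28/0.28/0.04).
#' @param magnitude_slope Logistic shift toward clinical per unit of
#'   exceedance (default 0.04 per mmHg).
#' @param use_magnitude Enable the severity covariate (default `TRUE`).
#' @return An `action_class_model`.
#' @export
action_class_model <- function(p_administrative = 0.77,
                               clinical_subtype_probs = c(
                                 phone_no_adjust = 0.40, phone_adjust = 0.28,
                                 message_no_adjust = 0.28, message_adjust = 0.04),
                               magnitude_slope = 0.04,
                               use_magnitude = TRUE) {
  if (p_administrative < 0 || p_administrative > 1)
    config_error("p_administrative must be in [0, 1]", "p_administrative")
  subtype_names <- c("phone_no_adjust", "phone_adjust",
                     "message_no_adjust", "message_adjust")
  if (!setequal(names(clinical_subtype_probs), subtype_names))
    config_error("clinical_subtype_probs must name the 4 subtypes",
                 "clinical_subtype_probs")
  if (any(clinical_subtype_probs < 0) ||
      abs(sum(clinical_subtype_probs) - 1) > 1e-8)
    config_error("clinical_subtype_probs must be >= 0 and sum to 1",
                 "clinical_subtype_probs")
  structure(list(
    p_administrative = p_administrative,
    clinical_subtype_probs = clinical_subtype_probs[subtype_names],
    magnitude_slope = magnitude_slope,
    use_magnitude = isTRUE(use_magnitude)
  ), class = "action_class_model")
}

#' Classify telemonitoring actions as administrative or clinical
#'
#' Seeded and reproducible: the same actions, model and seed give identical
#' labels.
#'
#' @param actions Output of [cluster_actions()].
#' @param model An [action_class_model()].
#' @param seed Integer seed for the classification draws.
#' @return Actions with `action_class` (`"administrative"`/`"clinical"`) and
#'   `clinical_subtype` (`"none"` for administrative actions).
#' @export
classify_actions <- function(actions, model = action_class_model(),
                             seed = 1L) {
  stopifnot(inherits(model, "action_class_model"))
  n <- nrow(actions)
  if (n == 0) {
    actions$action_class <- character()
    actions$clinical_subtype <- character()
    return(actions)
  }
  set.seed(as.integer(seed))
  x <- if ("max_exceedance" %in% names(actions)) actions$max_exceedance else rep(0, n)
  x[is.na(x)] <- 0
  p <- model$p_administrative
  s <- model$magnitude_slope
  p_admin <- if (model$use_magnitude && p > 0 && p < 1 && s != 0 &&
                 stats::sd(x) > 0) {
    # centre the logistic shift so the marginal administrative share is
    # exactly p_administrative: solve mean(plogis(qlogis(p) - s*(x - c))) = p
    f <- function(cc) mean(stats::plogis(stats::qlogis(p) - s * (x - cc))) - p
    cc <- stats::uniroot(f, lower = min(x) - 500, upper = max(x) + 500,
                         tol = 1e-10)$root
    stats::plogis(stats::qlogis(p) - s * (x - cc))
  } else {
    rep(p, n)
  }
  admin <- stats::runif(n) < p_admin
  subtype <- rep("none", n)
  n_clin <- sum(!admin)
  if (n_clin > 0) {
    subtype[!admin] <- sample(
      names(model$clinical_subtype_probs), n_clin, replace = TRUE,
      prob = model$clinical_subtype_probs)
  }
  actions$action_class <- ifelse(admin, "administrative", "clinical")
  actions$clinical_subtype <- subtype
  actions
}

#' E-nurse workload cost model
#'
#' @param minutes_administrative Minutes per administrative action (default 5).
#' @param minutes_clinical Minutes per clinical action, telephone or message
#'   (default 10).
#' @return A `workload_model`.
#' @export
workload_model <- function(minutes_administrative = 5, minutes_clinical = 10) {
  if (minutes_administrative <= 0 || minutes_clinical <= 0)
    config_error("workload minutes must be > 0", "minutes")
  structure(list(minutes_administrative = minutes_administrative,
                 minutes_clinical = minutes_clinical),
            class = "workload_model")
}

#' Total e-nurse workload of classified actions
#'
#' `minutes_administrative * n_administrative + minutes_clinical * n_clinical`,
#' with the per-class breakdown. Linear: the workload of a union of disjoint
#' action sets is the sum of their workloads.
#'
#' @param actions Classified actions (an unclassified action is a contract
#'   violation).
#' @param model A [workload_model()].
#' @return List: `total_minutes`, `n_administrative`, `n_clinical`,
#'   `minutes_administrative`, `minutes_clinical`.
#' @export
compute_workload <- function(actions, model = workload_model()) {
  if (nrow(actions) == 0) {
    return(list(total_minutes = 0, n_administrative = 0L, n_clinical = 0L,
                minutes_administrative = 0, minutes_clinical = 0))
  }
  if (!"action_class" %in% names(actions) || anyNA(actions$action_class))
    contract_error("compute_workload requires classified actions")
  n_adm <- sum(actions$action_class == "administrative")
  n_cli <- sum(actions$action_class == "clinical")
  list(
    total_minutes = model$minutes_administrative * n_adm +
      model$minutes_clinical * n_cli,
    n_administrative = n_adm, n_clinical = n_cli,
    minutes_administrative = model$minutes_administrative * n_adm,
    minutes_clinical = model$minutes_clinical * n_cli
  )
}

#' Workload from an alert count and an administrative proportion
#'
#' The proportion-mode workload formula used for alert-level projections:
#' `round_half_up(n * p * minutes_admin + n * (1 - p) * minutes_clinical)`.
#' The rounding is applied once, to the exact product — e.g. 1023 alerts at
#' p = 0.71 give 6598 minutes (not the 6600 that pre-rounded counts give).
#'
#' @param n_alerts Number of alerts (or actions) to cost.
#' @param p_administrative Proportion processed administratively, in `[0, 1]`.
#' @param model A [workload_model()].
#' @return Rounded total minutes (single number).
#' @examples
#' workload_from_proportions(1023, 0.71)  # 6598
#' workload_from_proportions(873, 0.71)   # 5631
#' @export
workload_from_proportions <- function(n_alerts, p_administrative,
                                      model = workload_model()) {
  if (p_administrative < 0 || p_administrative > 1)
    config_error("p_administrative must be in [0, 1]", "p_administrative")
  round_half_up(
    n_alerts * p_administrative * model$minutes_administrative +
      n_alerts * (1 - p_administrative) * model$minutes_clinical)
}
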