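#' Workflow policy
#'
#' Selects the reading workflow to simulate and how agreed recalls are
#' handled. Under `direct_recall` two effective readers who agree to recall
#' trigger a recall immediately; under `arbitrate` an arbiter makes the final
#' decision (site procedures differ on this point, so both are supported).
#'
#' @param variant One of `"DR"` (standard human double reading), `"sIR"`
#'   (AI is the second reader whenever it agrees with reader 1 in either
#'   direction) or `"DRT"` (AI is the second reader only when it agrees with
#'   reader 1 to not recall). On reader-1/AI disagreement both AI variants
#'   defer to standard double reading using the recorded second-reader and
#'   arbiter opinions.
#' @param agree_recall One of `"direct_recall"` or `"arbitrate"`.
#' @return A list of class `screenflow_policy`.
#' @export
workflow_policy <- function(variant = c("DR", "sIR", "DRT"),
                            agree_recall = c("direct_recall", "arbitrate")) {
  variant <- match.arg(variant)
  agree_recall <- match.arg(agree_recall)
  structure(list(variant = variant, agree_recall = agree_recall),
            class = "screenflow_policy")
}

decision_tibble <- function(cases, final, reads, second, arb, variant, policy) {
  tibble::tibble(
    case_id = cases$case_id,
    workflow = variant,
    policy = policy,
    final_recall = as.logical(final),
    human_reads = as.integer(reads),
    second_reader_used = as.logical(second),
    arbitration_used = as.logical(arb)
  )
}

# Core DR rule on explicit opinion vectors; shared by all three deciders.
dr_core <- function(r1, r2, arbiter, agree_recall) {
  disagree <- r1 != r2
  agree_yes <- r1 & r2
  arb_used <- disagree | (agree_yes & agree_recall == "arbitrate")
  final <- ifelse(arb_used, arbiter, agree_yes)
  reads <- 2L + as.integer(arb_used)
  list(final = final, reads = reads, arb = arb_used)
}

#' Standard double reading decision
#'
#' Two human readers read every case. Agreement not to recall ends the
#' episode; disagreement goes to arbitration; agreement to recall either
#' recalls directly or is arbitrated, per the policy. The AI opinion plays no
#' role and never changes the human read count.
#'
#' @param cases Cohort tibble (one or more rows).
#' @param policy A [workflow_policy()] with `variant = "DR"`.
#' @return A decision tibble with columns `case_id`, `workflow`, `policy`,
#'   `final_recall`, `human_reads`, `second_reader_used`, `arbitration_used`.
#' @export
decide_dr <- function(cases, policy = workflow_policy("DR")) {
  stopifnot(policy$variant == "DR")
  d <- dr_core(cases$r1_recall, cases$r2_recall, cases$arbiter_recall,
               policy$agree_recall)
  decision_tibble(cases, d$final, d$reads, TRUE, d$arb, "DR", policy$agree_recall)
}

#' Supporting independent reader (sIR) decision
#'
#' The AI is the effective second reader whenever it agrees with reader 1,
#' in either direction. Agreed no-recall ends the episode after a single
#' human read; agreed recall is recalled directly (or arbitrated, adding one
#' human read). On disagreement the case defers to standard double reading
#' using the recorded reader-2 and arbiter opinions, with reader 1 counted
#' once.
#'
#' @inheritParams decide_dr
#' @param policy A [workflow_policy()] with `variant = "sIR"`.
#' @return A decision tibble; see [decide_dr()].
#' @export
decide_sir <- function(cases, policy = workflow_policy("sIR")) {
  stopifnot(policy$variant == "sIR")
  r1 <- cases$r1_recall
  ai <- cases$ai_recall
  agree_no <- !r1 & !ai
  agree_yes <- r1 & ai

  dr <- dr_core(r1, cases$r2_recall, cases$arbiter_recall, policy$agree_recall)
  arbitrate_agreed <- policy$agree_recall == "arbitrate"

  final <- ifelse(agree_no, FALSE,
                  ifelse(agree_yes,
                         if (arbitrate_agreed) cases$arbiter_recall else TRUE,
                         dr$final))
  reads <- ifelse(agree_no, 1L,
                  ifelse(agree_yes, if (arbitrate_agreed) 2L else 1L, dr$reads))
  arb <- ifelse(agree_no, FALSE,
                ifelse(agree_yes, arbitrate_agreed, dr$arb))
  second <- !(agree_no | agree_yes)
  decision_tibble(cases, final, reads, second, arb, "sIR", policy$agree_recall)
}

#' Double reader triage (DRT) decision
#'
#' The AI is the effective second reader only when it agrees with reader 1
#' to not recall, ending the episode after one human read. Every other case
#' follows standard double reading on the recorded opinions.
#'
#' @inheritParams decide_dr
#' @param policy A [workflow_policy()] with `variant = "DRT"`.
#' @return A decision tibble; see [decide_dr()].
#' @export
decide_drt <- function(cases, policy = workflow_policy("DRT")) {
  stopifnot(policy$variant == "DRT")
  triaged <- !cases$r1_recall & !cases$ai_recall
  dr <- dr_core(cases$r1_recall, cases$r2_recall, cases$arbiter_recall,
                policy$agree_recall)
  final <- ifelse(triaged, FALSE, dr$final)
  reads <- ifelse(triaged, 1L, dr$reads)
  arb <- ifelse(triaged, FALSE, dr$arb)
  decision_tibble(cases, final, reads, !triaged, arb, "DRT", policy$agree_recall)
}

#' Additional-reader (XR) flag
#'
#' In the additional-reader workflow the AI flags, for extra human review,
#' cases that standard double reading did not recall. Retrospectively this is
#' the proxy for extra detection opportunity: a case is flagged iff the AI
#' recalls it and the DR decision did not.
#'
#' @param cases Cohort tibble.
#' @param dr_decisions Decision tibble produced by [decide_dr()] on the same
#'   cases (same order).
#' @return Logical vector, one flag per case.
#' @export
xr_flag <- function(cases, dr_decisions) {
  stopifnot(identical(cases$case_id, dr_decisions$case_id),
            all(dr_decisions$workflow == "DR"))
  cases$ai_recall & !dr_decisions$final_recall
}

#' Run a workflow over a cohort
#'
#' Order-preserving, pure dispatch to the per-variant decider.
#'
#' @param cases Cohort tibble.
#' @param policy A [workflow_policy()].
#' @return A decision tibble with one row per case, in input order.
#' @export
run_workflow <- function(cases, policy) {
  if (!inherits(policy, "screenflow_policy")) {
    config_error("policy", "must be a workflow_policy()")
  }
  switch(policy$variant,
         DR = decide_dr(cases, policy),
         sIR = decide_sir(cases, policy),
         DRT = decide_drt(cases, policy),
         config_error("variant", paste0("unknown workflow: ", policy$variant)))
}
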