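#' Comparison design for one stressor
#'
#' Defines the per-generation tests for a treatment: in each generation the
#' case replicates (default 3) are compared against the pooled control
#' samples of the matched experiment across all generations (default 9 =
#' controls from F1 + F2 + F4). Controls are matched within experiment, so
#' e.g. a zinc line run in experiment T2 is evaluated against the T2 control
#' line.
#'
#' @param sheet Sample sheet data.frame (sample_id, experiment, treatment,
#'   generation, clone_line).
#' @param treatment Stressor name present in the sheet.
#' @param generations Generations tested.
#' @return A `comparison_design` list with elements `treatment`,
#'   `experiment`, `generations`, `cases` (named list per generation),
#'   `control_pool` (all matched controls) and `controls_by_generation`.
#' @export
comparison_design <- function(sheet, treatment,
                              generations = c("F1", "F2", "F4")) {
  cs <- sheet[sheet$treatment == treatment & sheet$generation %in% generations, ]
  if (nrow(cs) == 0) stop("no samples for treatment ", treatment)
  experiment <- unique(cs$experiment)
  if (length(experiment) != 1)
    stop("treatment ", treatment, " spans multiple experiments")
  ct <- sheet[sheet$treatment == "control" & sheet$experiment == experiment &
                sheet$generation %in% generations, ]
  if (nrow(ct) == 0) stop("no matched control samples for ", treatment)
  cases <- lapply(stats::setNames(generations, generations),
                  function(g) cs$sample_id[cs$generation == g])
  if (any(vapply(cases, length, 1L) < 2))
    stop("each generation needs >= 2 case samples")
  if (length(intersect(unlist(cases), ct$sample_id)))
    stop("case and control sets overlap")
  structure(list(treatment = treatment, experiment = experiment,
                 generations = generations, cases = cases,
                 control_pool = ct$sample_id,
                 controls_by_generation = lapply(
                   stats::setNames(generations, generations),
                   function(g) ct$sample_id[ct$generation == g])),
            class = "comparison_design")
}

#' All samples entering a comparison
#' @param design A `comparison_design`.
#' @return Character vector of sample ids (cases in all generations, then
#'   the control pool).
#' @export
design_samples <- function(design) c(unlist(design$cases, use.names = FALSE),
                                     design$control_pool)
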