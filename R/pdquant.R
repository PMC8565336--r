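## Pharmacodynamic quantification: delta-delta-Ct relative expression,
## dual-luciferase normalization, percent silencing.

#' Relative expression by the delta-delta-Ct method
#'
#' Per well, `dCt = Ct_target - Ct_reference`; `ddCt` is `dCt` minus
#' the aggregated `dCt` of the control group (mean by default, the
#' convention when normalizing to vehicle-dosed controls; median via
#' `aggregate`); relative expression is `2^(-ddCt)`. Wells missing
#' either Ct are excluded with a message. Adding a constant to every Ct
#' (a machine offset) leaves the result unchanged, and the control
#' group's aggregated relative expression is 1 by construction.
#'
#' @param wells Data frame with columns `sample_id`, `group`,
#'   `ct_target`, `ct_reference`.
#' @param control_group Value of `group` identifying controls.
#' @param aggregate `"mean"` (default) or `"median"` control
#'   aggregation.
#' @return Data frame with per-well `dct`, `ddct`, `rel_expr`; group
#'   mean relative expressions are attached as attribute
#'   `group_means`.
#' @examples
#' w <- data.frame(sample_id = 1:4, group = c("control", "control", "t", "t"),
#'                 ct_target = c(24, 24, 27, 27), ct_reference = 20)
#' ddct_relative_expression(w, control_group = "control")
#' @export
ddct_relative_expression <- function(wells, control_group = "control",
                                     aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(wells)))
  ok <- is.finite(wells$ct_target) & is.finite(wells$ct_reference)
  if (any(!ok))
    message(sum(!ok), " well(s) excluded: missing or undetermined Ct")
  w <- wells[ok, , drop = FALSE]
  if (any(c(w$ct_target, w$ct_reference) <= 0))
    stop("Ct values must be positive")
  if (!any(w$group == control_group))
    stop("no wells in control group '", control_group, "'")
  agg <- if (aggregate == "mean") mean else stats::median
  w$dct <- w$ct_target - w$ct_reference
  ctrl <- agg(w$dct[w$group == control_group])
  w$ddct <- w$dct - ctrl
  w$rel_expr <- 2^(-w$ddct)
  gm <- tapply(w$rel_expr, w$group, mean)
  attr(w, "group_means") <- gm
  rownames(w) <- NULL
  w
}

#' Dual-luciferase normalization
#'
#' Within-well normalization of the Renilla (target-fused) signal to
#' the Firefly (transfection control) signal, scaled to the mean
#' Renilla/Firefly ratio of the reference condition (untreated or
#' non-targeting control wells), whose mean activity is therefore
#' exactly 1.
#'
#' @param wells Data frame with columns `sample_id`, `renilla`,
#'   `firefly`, `condition`.
#' @param reference_condition Value of `condition` defining the
#'   reference wells.
#' @return Data frame with `ratio` and `activity` columns; wells with
#'   non-positive Firefly signal are dropped with a message.
#' @export
luciferase_normalize <- function(wells, reference_condition = "untreated") {
  need <- c("sample_id", "renilla", "firefly", "condition")
  stopifnot(all(need %in% names(wells)))
  if (any(wells$renilla < 0, na.rm = TRUE))
    stop("negative Renilla signal")
  ok <- is.finite(wells$firefly) & wells$firefly > 0 & is.finite(wells$renilla)
  if (any(!ok))
    message(sum(!ok), " well(s) invalid (Firefly <= 0 or missing signal)")
  w <- wells[ok, , drop = FALSE]
  if (!any(w$condition == reference_condition))
    stop("no wells in reference condition '", reference_condition, "'")
  w$ratio <- w$renilla / w$firefly
  ref <- mean(w$ratio[w$condition == reference_condition])
  w$activity <- w$ratio / ref
  rownames(w) <- NULL
  w
}

#' Percent silencing from relative expression
#'
#' `100 * (1 - x)`, floored at 0 for display (a relative expression
#' above 1 means no silencing, not negative silencing); the unfloored
#' value is kept in the `"raw"` attribute.
#'
#' @param x Relative expression (fold of control), `x >= 0`.
#' @return Percent knockdown on the 0-100 scale.
#' @examples
#' percent_silencing(0.13)  # 87
#' @export
percent_silencing <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  raw <- 100 * (1 - x)
  out <- pmax(raw, 0)
  attr(out, "raw") <- raw
  out
}
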