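#' The 19-facility OPTIMISTIC analytic dataset
#'
#' The analytic case table of the OPTIMISTIC nursing-facility demonstration
#' project: 19 Indiana nursing facilities, their all-cause hospitalization
#' rates per 1,000 eligible resident days before (Jan 2011 - Jun 2012) and
#' during (Jan 2015 - Jun 2016) the intervention, two binary improvement
#' outcomes (relative decline of at least 10% and at least 20%), and four
#' crisp implementation conditions:
#'
#' * `don_turnover` — one or more turnovers in the director of nursing
#'   during the observation period;
#' * `support` — project-nurse rating that senior management supported the
#'   program through investment of resources (agree/strongly agree = 1);
#' * `low_baseline` — membership in the quartile of facilities with the
#'   lowest baseline hospitalization rates (the "top performers", with the
#'   least room for improvement);
#' * `chess` — average CHESS acuity score of 1 or more (less stable, sicker
#'   residents).
#'
#' The printed outcome columns are reproducible from the rate columns with
#' [derive_decline_outcomes()] and the `low_baseline` column from
#' `pre_rate` with [dichotomize_by_quantile()].
#'
#' @return a [case_table()] with 19 cases, four crisp conditions, two
#'   numeric rate columns and two outcomes.
#' @examples
#' ct <- optimistic_facilities()
#' consistency(conjunction(don_turnover = 1), ct, "decline10")
#' @export
optimistic_facilities <- function() {
  load_case_table(
    system.file("extdata", "optimistic_facilities.csv", package = "csqca",
                mustWork = TRUE),
    system.file("extdata", "optimistic_schema.json", package = "csqca",
                mustWork = TRUE))
}
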