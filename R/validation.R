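## Wet-lab validation arithmetic: competition-assay specific uptake and
## knockout / wild-type SUV ratios from small-animal PET.

#' Specific uptake from a competition assay
#'
#' Specific uptake = total uptake minus nonspecific uptake (the uptake
#' remaining under excess cold-ligand competition). Negative differences
#' are reported as-is — assay noise around zero, not clamped — with a
#' warning flag in the result.
#'
#' @param uptake Tibble with columns `total` and `nonspecific`
#'   (non-negative counts); any other columns (e.g. `cell_line`) are kept.
#' @return The input with columns `specific` and `noise_flag` (`TRUE` where
#'   the difference is negative) appended.
#' @export
#' @examples
#' specific_uptake(tibble::tibble(cell_line = "KB", total = 1000, nonspecific = 400))
specific_uptake <- function(uptake) {
  stopifnot(
    all(c("total", "nonspecific") %in% names(uptake)),
    all(is.finite(uptake$total)), all(is.finite(uptake$nonspecific)),
    all(uptake$total >= 0), all(uptake$nonspecific >= 0)
  )
  dplyr::mutate(
    uptake,
    specific = .data$total - .data$nonspecific,
    noise_flag = .data$specific < 0
  )
}

#' Read an SUV summary table
#'
#' CSV with columns `group` (`knockout` / `wild_type`), `region`,
#' `statistic` (`SUVpeak` / `SUVmax`), `mean`, `sd`, `n`. The packaged
#' fixture `table2_suv.csv` holds the knockout vs wild-type parotid/muscle
#' summary (n = 3 per group).
#'
#' @param path Path to the CSV; default the packaged fixture.
#' @return Tibble of SUV summaries.
#' @export
read_suv_table <- function(path = system.file("extdata", "table2_suv.csv",
                             package = "psmascreen")) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(
    all(c("group", "region", "statistic", "mean", "sd") %in% names(tbl)),
    all(tbl$mean >= 0), all(tbl$sd >= 0)
  )
  tbl
}

#' Knockout / wild-type SUV ratio
#'
#' 100 x mean(knockout SUVs over the region set) / mean(wild-type SUVs over
#' the region set). With both parotids this is the bilateral-mean uptake
#' ratio of PSMA-null to wild-type mice.
#'
#' @param suv SUV tibble from [read_suv_table()].
#' @param statistic `"SUVpeak"` or `"SUVmax"`.
#' @param regions Character vector of regions to average (default both
#'   parotids).
#' @return Ratio in percent (a single number).
#' @export
#' @examples
#' suv_ratio(read_suv_table(), "SUVpeak")
suv_ratio <- function(suv, statistic = c("SUVpeak", "SUVmax"),
                      regions = c("right_parotid", "left_parotid")) {
  statistic <- match.arg(statistic)
  pick <- function(grp) {
    rows <- suv[suv$group == grp & suv$statistic == statistic & suv$region %in% regions, ]
    if (nrow(rows) != length(regions)) {
      rlang::abort(sprintf("missing %s cells for group '%s'", statistic, grp))
    }
    mean(rows$mean)
  }
  ko <- pick("knockout")
  wt <- pick("wild_type")
  if (wt == 0) rlang::abort("wild-type mean is zero: ratio undefined")
  100 * ko / wt
}
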