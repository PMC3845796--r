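#' Published Go/Explore/NoGo and utility parameters
#'
#' Returns the calibrated action-selection parameters for a study and
#' patient group, read from the parameter files shipped with the package:
#' `table3.yaml` (the light-object lift study: control and PD ON) and
#' `table4.yaml` (the medication/surface study: control, PD OFF, PD ON;
#' shared across silk and sandpaper).
#'
#' @param table `"table3"` (alias `"fellows"`) or `"table4"` (alias
#'   `"ingvarsson"`).
#' @param group `"control"`, `"pd_off"` or `"pd_on"`.
#' @return a list with a [gen_params()] object (`$gen`), the risk weight
#'   `$alpha`, and the dopamine condition values `$delta_lim`, `$delta_med`.
#' @examples
#' gen_param_table("table3", "pd_on")$alpha # 0.312
#' @export
gen_param_table <- function(table = c("table3", "fellows", "table4",
                                      "ingvarsson"),
                            group = c("control", "pd_off", "pd_on")) {
  table <- match.arg(table)
  group <- match.arg(group)
  file <- if (table %in% c("table3", "fellows")) "table3.yaml" else "table4.yaml"
  tab <- yaml::read_yaml(system.file("extdata", file, package = "gripsim",
                                     mustWork = TRUE))
  if (!group %in% names(tab))
    stop("group '", group, "' is not tabulated for ", table)
  row <- tab[[group]]
  list(gen = gen_params(A_G = row$a_g, A_N = row$a_n, A_E = row$a_e,
                        lambda_G = row$lambda_g, lambda_N = row$lambda_n,
                        sigma_E = row$sigma_e),
       alpha = row$alpha, delta_lim = row$delta_lim,
       delta_med = row$delta_med)
}

#' Dopamine condition for a tabulated study group
#'
#' @param table,group as in [gen_param_table()].
#' @return a [dopamine_condition()] with the tabulated clamp and shift.
#' @export
condition_from_table <- function(table, group) {
  p <- gen_param_table(table, group)
  dopamine_condition(group, delta_lim = p$delta_lim, delta_med = p$delta_med)
}
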