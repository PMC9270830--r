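#' Published salience rankings from a two-period medicinal-plant survey
#'
#' Per-plant cultural salience and null-model p-values transcribed from a
#' published free-list study of medicinal-plant knowledge in Vale do
#' Catimbau (Caatinga, NE Brazil): the same 49 residents of five rural
#' communities interviewed in 2017 (`"period1"`, 81 plants) and 2019
#' (`"period2"`, 77 plants), and a same-period generational contrast in one
#' community between 25 adults (`"adults"`, 53 plants) and 18
#' children/adolescents (`"children"`, 22 plants). Plants are vernacular
#' names, ordered by decreasing salience; p-values are the published
#' rank-matched null-model values, so [classify_core()] applied to these
#' tables reproduces the published structural-core sizes (15, 11, 9 and 2).
#'
#' @param table One of `"period1"`, `"period2"`, `"adults"`, `"children"`.
#' @return A data frame of class `"salience_table"` with columns `rank`,
#'   `item`, `salience`, `p_value`.
#' @examples
#' tab <- published_salience("children")
#' attr(classify_core(tab), "core_size")  # 2
#' @export
published_salience <- function(table = c("period1", "period2", "adults",
                                         "children")) {
  table <- match.arg(table)
  file <- system.file("extdata", paste0("salience_", table, ".csv"),
                      package = "ethnocore", mustWork = TRUE)
  out <- utils::read.csv(file, stringsAsFactors = FALSE, encoding = "UTF-8")
  class(out) <- c("salience_table", "data.frame")
  out
}
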