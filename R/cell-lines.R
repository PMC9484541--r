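#' Registry of the 20 digestive-system cell lines
#'
#' One row per cell line, mapping it to its organ of origin. The registry
#' covers six organs: esophagus, stomach, colon, bile duct, liver, and
#' pancreas, with 17 cancer lines and 3 normal lines (GES-1, HIBEpiC, L-02).
#' Every viability dataset is validated against this table: a record's
#' `cell_line` must appear here and its `organ` must agree.
#'
#' @return A tibble with columns `organ` and `cell_line`.
#' @export
#' @examples
#' cell_lines()
cell_lines <- function() {
  tibble::tribble(
    ~organ,      ~cell_line,
    "esophagus", "KYSE-150",
    "esophagus", "KYSE-410",
    "stomach",   "GES-1",
    "stomach",   "MGC-823",
    "stomach",   "SGC-7901",
    "stomach",   "MKN-45",
    "colon",     "SW-620",
    "colon",     "SW-480",
    "colon",     "HCT-116",
    "colon",     "LoVo",
    "bile_duct", "HIBEpiC",
    "bile_duct", "HuCCT-1",
    "bile_duct", "QBC-939",
    "bile_duct", "HCCC-9810",
    "liver",     "L-02",
    "liver",     "Huh-7",
    "liver",     "Hep-3B",
    "liver",     "Hep-G2",
    "pancreas",  "PANC-1",
    "pancreas",  "MIA PaCa-2"
  )
}

# canonical organ ordering used for coefficient tables (display order)
organ_levels <- function() {
  c("esophagus", "stomach", "colon", "liver", "bile_duct", "pancreas")
}
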