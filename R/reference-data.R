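# Reference measurements from the diceCT staining-optimization study of a
# cartilaginous fish (brownbanded bamboo shark) and a bony fish (common
# goldfish), shipped as plain-text inputs for validating the summary
# arithmetic.

#' Reference per-region shrinkage measurements
#'
#' Linear tissue-shrinkage percentages (between the unstained scan and the
#' final staining time point) for the four brain regions sampled — olfactory
#' bulbs (OBs), telencephalon (Tel), cerebellum (Cer) and medulla oblongata
#' (Med) — in three specimens each of a bamboo shark (*Chiloscyllium
#' punctatum*) and a goldfish (*Carassius auratus*), as published in the
#' staining-optimization study this package's methods reproduce.
#' [summarize_shrinkage()] on this table recovers the published region and
#' overall means.
#'
#' @return A tibble: `species`, `region`, `specimen`, `percent`.
#' @export
#' @examples
#' summarize_shrinkage(reference_shrinkage())
reference_shrinkage <- function() {
  readr::read_csv(system.file("extdata", "shrinkage_by_region.csv",
                              package = "dicect", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reference whole-brain mean tissue widths
#'
#' Published whole-brain mean brain-tissue widths (four slices pooled, three
#' specimens per species) at the first and last staining time points:
#' the shark's mean width fell from 5.46 mm (unstained) to 4.78 mm at 240 h,
#' the goldfish's from 2.38 mm to 1.90 mm at 96 h. Feeding a row's widths to
#' [shrinkage_percent()] gives the species-level whole-brain shrinkage.
#'
#' @return A tibble: `species`, `start_time_h`, `end_time_h`,
#'   `start_width_mm`, `end_width_mm`.
#' @export
reference_whole_brain_widths <- function() {
  tibble(
    species = c("Chiloscyllium punctatum", "Carassius auratus"),
    start_time_h = c(0, 0),
    end_time_h = c(240, 96),
    start_width_mm = c(5.46, 2.38),
    end_width_mm = c(4.78, 1.90)
  )
}
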