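#' Published per-patient benchmark averages
#'
#' Per-patient average PSNR and average-gradient values reported in the
#' published evaluation of the five enhancement methods (global HE,
#' morphological opening and closing enhancement, CLAHE, and the
#' correlation-histogram method) on 211 brain MR images from ten patients.
#' The underlying images are not publicly deposited, so only these
#' per-patient means — and the consistency of their grand averages — are
#' reproducible; they are shipped as reference data for the comparison
#' harness.
#'
#' @param metric `"psnr"` or `"gradient"`.
#' @return data frame with columns `patient`, `n_images`, `he`, `opening`,
#'   `closing`, `clahe`, `hcha`.
#' @export
benchmark_table <- function(metric = c("psnr", "gradient")) {
  metric <- match.arg(metric)
  path <- system.file("extdata", sprintf("benchmark_%s.csv", metric),
                      package = "hcha", mustWork = TRUE)
  utils::read.csv(path)
}

#' Grand-average row of a benchmark table
#'
#' Applies [grand_average()] to each method column and rounds to the
#' 2-decimal display precision of the published tables.
#'
#' @inheritParams benchmark_table
#' @return named numeric vector over the five methods.
#' @export
benchmark_grand_averages <- function(metric = c("psnr", "gradient")) {
  tab <- benchmark_table(metric)
  cols <- c("he", "opening", "closing", "clahe", "hcha")
  vapply(tab[cols], function(x) round(grand_average(x), 2), numeric(1))
}
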