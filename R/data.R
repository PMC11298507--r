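#' Published per-case airway segmentation DSC table
#'
#' Per-case volume DSC (%) for ten validation cases under three 2D baseline
#' models (`nnunet_in_lrelu`, `nnunet_bn_relu`, `dilated_unet`), each with the
#' single-scale baseline (ir = 1) and the four-ratio ensemble
#' (ir1 + ir2 + ir4 + ir8). Used as the input for the gain/aggregation
#' arithmetic ([performance_gain()], [ablation_summary()]); the underlying CT
#' scans are not distributable, so only this printed summary ships.
#'
#' @param model optional filter: one of the model names above.
#' @return data frame with columns `case`, `model`, `baseline`, `ensemble`.
#' @export
airway_dsc_table <- function(model = NULL) {
  path <- system.file("extdata", "airway_dsc_cases.csv", package = "interpsplit",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(model)) {
    if (!model %in% df$model) stop("unknown model: ", model, call. = FALSE)
    df <- df[df$model == model, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
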