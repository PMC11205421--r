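# Shared fixtures: the default panel and a few shortcuts used across files.

panel <- default_panel()
t_spec <- panel[["T"]]
t4_spec <- panel[["T4"]]
thr <- threshold_config()

# a minimal single-analyte panel around testosterone, for fast simulations
t_panel <- local({
  specs <- list(panel[["T"]])
  names(specs) <- "T"
  structure(specs, class = "vams_panel")
})

# noise model with chosen injected parameters for one analyte
inject_noise <- function(panel, analyte, intraday = NULL, interday = NULL,
                         recovery = NULL, me = NULL) {
  nm <- default_noise_model(panel)
  i <- match(analyte, nm$analyte)
  if (!is.null(intraday)) nm$intraday_cv_pct[i] <- intraday
  if (!is.null(interday)) nm$interday_cv_pct[i] <- interday
  if (!is.null(recovery)) nm$recovery_pct[i] <- recovery
  if (!is.null(me)) nm$matrix_effect_pct[i] <- me
  nm
}
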