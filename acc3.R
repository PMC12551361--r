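suppressMessages(devtools::load_all("/root/pkg", quiet=TRUE))
t0 <- proc.time()[3]
cfg <- sim_config()  # defaults: n=10,000 persons, 6 biennial waves, gold 0.1
gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = cfg$seed)
pan <- suppressMessages(simulate_panel(cfg, gdp))
obs <- degrade_to_observables(pan, cfg)
gold <- assign_gold_standard(obs, cfg$gold_fraction, seed = cfg$seed)
res <- classify_dementia(obs, gold)
cat("probit validity:", res$validity$accuracy, " by kind:", res$validity$by_kind, "\n")
cat("cutoff:", res$cutoff, " time:", proc.time()[3]-t0, "\n")
# MLP per kind on gold calibration, evaluated on gold validation
cal <- gold[gold$split=="calibration",]
accs <- c()
for (kd in c("self","proxy")) {
  fs <- build_features(obs, kd)
  idx <- apcdem:::match_gold_rows(fs$meta, cal); ok <- !is.na(idx)
  fit <- train_mlp(fs$X[idx[ok],], cal$label[ok], mlp_spec(seed=cfg$seed))
  rep <- evaluate_mlp(fit, fs, gold)
  cat(kd, "mlp validity:", rep$accuracy, "n:", rep$n, "\n")
  accs[kd] <- rep$accuracy
}
# pooled mlp validity across kinds
preds <- NULL
cat("total time:", proc.time()[3]-t0, "\n")
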