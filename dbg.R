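suppressMessages(devtools::load_all("/root/pkg", quiet=TRUE))
cfg <- sim_config()
gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = cfg$seed)
pan <- suppressMessages(simulate_panel(cfg, gdp))
obs <- degrade_to_observables(pan, cfg)
gold <- assign_gold_standard(obs, cfg$gold_fraction, seed = cfg$seed)
cat("gold rows:", nrow(gold), " val:", sum(gold$split=="validation"), "\n")
fs_s <- build_features(obs, "self"); fs_p <- build_features(obs, "proxy")
val <- gold[gold$split=="validation",]
ms <- apcdem:::match_gold_rows(fs_s$meta, val); mp <- apcdem:::match_gold_rows(fs_p$meta, val)
cat("matched self:", sum(!is.na(ms)), " proxy:", sum(!is.na(mp)), " both NA:", sum(is.na(ms)&is.na(mp)), "\n")
bad <- val[is.na(ms)&is.na(mp),]
print(head(bad))
cat("rows in obs for first bad:", sum(obs$person_id==bad$person_id[1] & obs$wave==bad$wave[1]), "\n")
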