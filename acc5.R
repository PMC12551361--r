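suppressMessages(devtools::load_all("/root/pkg", quiet=TRUE))
source("/root/pkg/tests/testthat/helper-fixtures.R")
# ordering: 3 reps at n_persons=10,000
t0 <- proc.time()[3]
ok <- 0
for (r in 1:3) {
  des <- mc_design(10000, seed = 100 + r)
  f <- fit_glmm(des, se = "none", start = unname(mc_truth(des)))
  co <- f$coefficients[grep("^cohort_", names(f$coefficients))]
  if (all(co < 0) && all(diff(co) < 0)) ok <- ok + 1
}
cat("ordering 3 reps:", (proc.time()[3]-t0)/3, "s/rep, ok:", ok, "\n")
# coverage: 5 reps at n_persons=2,000
t0 <- proc.time()[3]
cover <- c()
truth <- c(-0.2, -0.3, -0.5)
for (r in 1:5) {
  des <- mc_design(2000, seed = 300 + r)
  f <- fit_glmm(des, start = unname(mc_truth(des)))
  co <- grep("^cohort_", names(f$coefficients))
  cover <- c(cover, f$ci95[co, "low"] <= truth & truth <= f$ci95[co, "high"])
}
cat("coverage 5 reps:", (proc.time()[3]-t0)/5, "s/rep, cover:", mean(cover), "\n")
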