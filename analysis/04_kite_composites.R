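#!/usr/bin/env Rscript
# Composite trade-off (kite) scores: invert starred indicators, normalise
# jointly over strategies and years so the best value is 1, aggregate to the
# six objective classes, and export kite data for the last historical and
# final projection years. Requires 03_ensemble_bands.R to have run.

suppressMessages(library(shelfmse))
stopifnot(file.exists("results/ensemble_indicators.csv"))
ind <- utils::read.csv("results/ensemble_indicators.csv",
                       stringsAsFactors = FALSE)
pb <- c(burn_in_end = 10, historical_end = 20, final = 60)

# member-0 (best-fit) kites
ind0 <- ind[ind$member == 0, ]
kk <- ensemble_kites(ind0, pb)
utils::write.csv(kk$scores, "results/composite_scores.csv", row.names = FALSE)
jsonlite::write_json(kk$kites, "results/kite_data.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

fin <- kk$scores[kk$scores$year == pb[["final"]], ]
wide <- stats::reshape(fin[, c("strategy", "class", "score")],
                       idvar = "class", timevar = "strategy",
                       direction = "wide")
names(wide) <- sub("score\\.", "", names(wide))
cat("Final-year composite class scores (best-fit member, 1 = best):\n")
print(wide, digits = 2, row.names = FALSE)

# the qualitative trade-off pattern, member by member
n_pass <- 0
for (m in sort(unique(ind$member))) {
  sc <- ensemble_kites(ind[ind$member == m, ], pb)$scores
  f <- sc[sc$year == pb[["final"]], ]
  get <- function(cl, s) f$score[f$class == cl & f$strategy == s]
  ss <- unique(f$strategy)
  eco <- vapply(ss, function(s) get("ecological", s), numeric(1))
  econ <- vapply(ss, function(s) get("economic", s), numeric(1))
  worst <- vapply(unique(f$class), function(cl)
    ss[which.min(vapply(ss, function(s) get(cl, s), numeric(1)))],
    character(1))
  n_pass <- n_pass + (names(which.max(eco)) == "S4_conservation" &&
    names(which.min(eco)) == "S1_status_quo" &&
    names(which.min(econ)) == "S4_conservation" &&
    !("S3_integrated" %in% worst))
}
cat(sprintf("\nTrade-off pattern (S4 best ecological / worst economic, S1 worst\necological, S3 nowhere worst) holds in %d of %d ensemble members.\n",
            n_pass, length(unique(ind$member))))
cat("\nwrote results/composite_scores.csv and results/kite_data.json\n")
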