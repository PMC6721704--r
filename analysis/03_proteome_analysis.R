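#!/usr/bin/env Rscript
# The statistical layer over the simulated study set: abundance and length
# stratifications, operon dispersion and LA/HA essentiality, subcellular
# location, surface composition of the score deciles, and the SSI analysis
# by oligomeric state.  Writes one TSV/JSON per analysis under results/.

suppressMessages(library(stapr))

if (!file.exists("results/proteome.tsv")) {
  stop("run analysis/01_simulate.R first")
}
tab <- read_proteome_table("results/proteome.tsv")
seed <- 1L

## abundance and length --------------------------------------------------------
ab <- run_analysis(tab, "abundance", seed = seed)
cat(sprintf("abundance: r = %.3f (p = %.3g); 25%% least vs most abundant STAP p = %.3g\n",
            ab$correlation$r, ab$correlation$p_value, ab$stap$test$p_value))
ln <- run_analysis(tab, "length", seed = seed)
cat(sprintf("length: shortest vs longest quartile STAP p = %.3g (SD %.2f vs %.2f)\n",
            ln$stap$test$p_value, ln$stap$summary["low", "sd"],
            ln$stap$summary["high", "sd"]))
utils::write.table(
  rbind(cbind(analysis = "abundance", as.data.frame(ab$stap$summary)),
        cbind(analysis = "length", as.data.frame(ln$stap$summary))),
  "results/stratification_summaries.tsv", sep = "\t", quote = FALSE)

## operons ---------------------------------------------------------------------
op <- run_analysis(tab, "operon", seed = seed)
cat(sprintf("operons: %.0f%% of %d operons below the global SD (perm p = %.3g)\n",
            100 * op$dispersion$fraction_below, op$dispersion$n_operons,
            op$dispersion$perm_p))
print(op$la_ha$counts)
utils::write.table(op$dispersion$operon_sd, "results/operon_sd.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## location --------------------------------------------------------------------
loc <- run_analysis(tab, "location", seed = seed)
loc_tab <- do.call(rbind, lapply(names(loc$by_location), function(l)
  data.frame(location = l, t(loc$by_location[[l]]))))
utils::write.table(loc_tab, "results/location_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("mean STAP by location:\n")
print(loc_tab[order(-loc_tab$mean), c("location", "n", "mean")],
      row.names = FALSE)

## surface composition -----------------------------------------------------------
prof <- function(grp) {
  files <- list.files(file.path("results/structures", grp),
                      full.names = TRUE)
  lapply(files, function(f) relative_exposure(read_structure(f, "A")))
}
cmp <- suppressWarnings(
  surface_composition_compare(prof("low"), prof("high")))
utils::write.table(cmp, "results/surface_composition.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
sig <- cmp[cmp$p_value <= 0.01, ]
cat(sprintf("composition: %d/20 amino acids differ at p <= 0.01 (%s in soluble; %s in aggregation-prone)\n",
            nrow(sig),
            paste(sig$aa[sig$direction == "low"], collapse = ""),
            paste(sig$aa[sig$direction == "high"], collapse = "")))

## supersaturation -----------------------------------------------------------------
ss <- run_analysis(tab, "ssi", seed = seed)
cat(sprintf("SSI monomers vs oligomers: p = %.3g\n", ss$ssi$test$p_value))
print(round(ss$ssi$percentages, 1))
write_manifest(list(abundance = ab$manifest, length = ln$manifest,
                    operon = op$manifest, ssi = ss$manifest),
               "results/analysis_manifest.json")
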