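#!/usr/bin/env Rscript
# Stage 5: disorder similarity and its molecular/connectomic correlates.
#
# Builds the region x region disorder-similarity matrix from the 13
# synthetic maps, quantifies each disorder's leave-one-out influence,
# compares disorder similarity against molecular and connectomic feature
# similarity (spin test) and against the structural network
# (connected/unconnected contrast vs rewired nulls) and the intrinsic
# networks (within/between contrast vs spins), and repeats the key
# comparison with distance regression instead of the spin test.

suppressMessages(library(vulnmap))

seed <- 1L
in_dir <- "results/synthetic"
out_dir <- "results"
parc <- read_parcellation(file.path(in_dir, "parcellation.tsv"))
consensus <- read_matrix(file.path(in_dir, "sc_consensus_binary.tsv"), parc)
fcn <- read_matrix(file.path(in_dir, "fc.tsv"), parc, kind = "functional")
mol <- zscore_columns(read_region_table(
  file.path(in_dir, "molecular_predictors.tsv"), parc, family = "molecular"))
con <- zscore_columns(read_region_table(
  file.path(in_dir, "connectomic_predictors.tsv"), parc,
  family = "connectomic"))
map_files <- sort(list.files(file.path(in_dir, "maps"), full.names = TRUE))
maps <- lapply(map_files, read_region_table, parc = parc)

sim <- disorder_similarity(maps)
cat(sprintf("disorder similarity: %d regions, %d unique pairs\n",
            sim$n_regions, length(upper_values(sim))))

inf <- influence(maps)
utils::write.table(data.frame(disorder = names(inf), influence = inf,
                              loo_correlation = attr(inf, "loo_correlation")),
                   file.path(out_dir, "influence.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("leave-one-out: min correlation with full matrix %.3f (max influence %.4f)\n",
            min(attr(inf, "loo_correlation")), max(inf)))

spins <- generate_spins(parc, n = 1000, seed = seed)
rows <- list()
for (cmp in list(list(name = "molecular", other = feature_similarity(mol)),
                 list(name = "connectomic", other = feature_similarity(con)),
                 list(name = "fc", other = fcn))) {
  mc <- matrix_correlation(sim, cmp$other, spins)
  rows[[cmp$name]] <- data.frame(comparison = cmp$name, r = mc$r,
                                 p_spin = mc$p_spin, n_pairs = mc$n_pairs)
  cat(sprintf("disorder similarity vs %s: r(%d) = %.3f, p_spin = %.4f\n",
              cmp$name, mc$n_pairs - 2, mc$r, mc$p_spin))
}
utils::write.table(do.call(rbind, rows),
                   file.path(out_dir, "similarity_comparisons.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# distance-regressed variant of the molecular comparison
res_sim <- distance_regress(sim, parc)
res_mol <- distance_regress(feature_similarity(mol), parc)
ut <- upper.tri(res_sim)
cat(sprintf("distance-regressed molecular comparison: r = %.3f\n",
            stats::cor(res_sim[ut], res_mol[ut])))

# network contrasts
nulls <- suppressWarnings(rewire_preserving(consensus, parc,
                                            n_ensembles = 500, seed = seed))
cu <- connected_vs_unconnected(sim, consensus, nulls)
cat(sprintf("connected vs unconnected similarity: diff = %.4f, p = %.3f (n = %d / %d)\n",
            cu$diff, cu$p, cu$n_connected, cu$n_unconnected))
wb <- within_between_networks(sim, parc$network_id, spins)
cat(sprintf("within vs between networks: diff = %.4f, p_spin = %.3f (n = %d / %d)\n",
            wb$diff, wb$p_spin, wb$n_within, wb$n_between))
utils::write.table(
  data.frame(contrast = c("connected_vs_unconnected", "within_vs_between"),
             diff = c(cu$diff, wb$diff), p = c(cu$p, wb$p_spin),
             n_a = c(cu$n_connected, wb$n_within),
             n_b = c(cu$n_unconnected, wb$n_between)),
  file.path(out_dir, "network_contrasts.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
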