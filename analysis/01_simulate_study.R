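#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Builds a 68-region mirrored spherical parcellation, a 70-subject cohort
# of distance-dependent structural connectomes, seven spatially smooth
# molecular predictor maps, and thirteen synthetic disorder abnormality
# maps with known ground truth: eight driven linearly by the molecular
# predictors (planted population R^2 between 0.2 and 0.8) and five by
# network diffusion from a planted epicentre. Writes everything as
# delimited tables under results/synthetic/ together with a ground-truth
# manifest.

suppressMessages(library(vulnmap))

seed <- 1L
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- synth_spec(seed = seed)
parc <- make_parcellation(spec)
write_parcellation(parc, file.path(out_dir, "parcellation.tsv"))
cat(sprintf("parcellation: %d regions, %d networks\n", parc$n_regions,
            length(unique(parc$network_id))))

stack <- make_subject_connectomes(parc, spec)
cat(sprintf("cohort: %d subjects, mean binary density %.3f (target %.2f)\n",
            length(stack), mean(vapply(stack, network_density, numeric(1))),
            spec$target_density))
subj_dir <- file.path(out_dir, "subjects")
dir.create(subj_dir, showWarnings = FALSE)
for (i in seq_along(stack))
  write_matrix(stack[[i]], file.path(subj_dir, sprintf("subject_%02d.tsv", i)))

# consensus SC is built properly in stage 2; here we only need a weighted
# SC for the diffusion forward model
consensus <- suppressWarnings(group_consensus(stack, parc))
sc <- weight_consensus(stack, consensus, parc)
fc <- make_fc(sc, parc, coupling = 0.6, seed = seed + 1)
write_matrix(fc, file.path(out_dir, "fc.tsv"))

mol <- make_smooth_maps(parc, 7, autocorr_length = spec$autocorr_length,
                        seed = seed + 2)
mol$column_names <- colnames(mol$matrix) <-
  c("gene_pc1", "receptor_pc1", "ei_ratio", "glycolytic_index",
    "glucose_metabolism", "synapse_density", "myelination")
write_region_table(mol, file.path(out_dir, "molecular_predictors.tsv"), parc)

# thirteen disorder maps: 8 linear-molecular, 5 diffusion-seeded
set.seed(seed + 3)
manifest <- list()
maps_dir <- file.path(out_dir, "maps")
dir.create(maps_dir, showWarnings = FALSE)
planted_r2 <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.6)
for (k in 1:8) {
  betas <- stats::rnorm(7)
  nsd <- noise_for_r2(mol, betas, planted_r2[k])
  m <- make_abnormality_linear(mol, parc, betas, nsd, seed = seed + 10 + k)
  m$name <- sprintf("disorder_%02d", k)
  write_region_table(m, file.path(maps_dir, sprintf("disorder_%02d.tsv", k)),
                     parc)
  manifest[[k]] <- data.frame(disorder = m$name, kind = "linear",
                              planted_r2 = attr(m, "planted_r2"),
                              epicentre = NA_integer_)
}
epis <- sample.int(parc$n_regions, 5)
for (k in 9:13) {
  m <- make_abnormality_diffusion(sc, parc, epis[k - 8], alpha = 0.4,
                                  noise_sd = 0.1, seed = seed + 10 + k)
  m$name <- sprintf("disorder_%02d", k)
  write_region_table(m, file.path(maps_dir, sprintf("disorder_%02d.tsv", k)),
                     parc)
  manifest[[k]] <- data.frame(disorder = m$name, kind = "diffusion",
                              planted_r2 = NA_real_,
                              epicentre = epis[k - 8])
}
manifest <- do.call(rbind, manifest)
utils::write.table(manifest, file.path(out_dir, "ground_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote 13 disorder maps (8 linear, 5 diffusion-seeded) and manifest\n")
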