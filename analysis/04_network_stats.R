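#!/usr/bin/env Rscript
## Functional-connectivity statistics on the back-reconstructed maps:
## z-scored one-sample t maps per condition (FDR q < 0.01), paired t maps
## in native map scale, cluster extraction (uncorrected p < 0.005, extent
## >= 20 voxels, 26-connectivity), and 27-voxel ROI definition at the top
## paired-t peaks.

library(restconn)
cohort <- readRDS("scratch/cohort.rds")
ica <- readRDS("scratch/ica.rds")
m <- read.delim("results/ica_matching.tsv")
grid <- cohort$truth$sources$grid
cond <- sub("^.*\\.", "", names(ica$subject_maps))

cluster_rows <- NULL
rois <- list()
for (i in seq_len(nrow(m))) {
  net <- m$network[i]; comp <- m$component[i]
  maps <- t(vapply(ica$subject_maps, function(mm) mm[, comp],
                   numeric(n_voxels(grid))))
  for (cc in c("abstinence", "satiety")) {
    z <- t(apply(maps[cond == cc, ], 1, zscore_map))
    os <- one_sample_ttest(z, grid)
    fdr <- fdr_threshold(os$p, 0.01)
    in_mask <- cohort$truth$sources$masks[, net]
    act <- fdr$reject & os$t > 0    # activation side of the two-sided test
    cat(sprintf("%s %s: one-sample FDR q<0.01, %d suprathreshold voxels; covers %.0f%% of the template mask\n",
                net, cc, sum(act), 100 * mean(act[in_mask])))
  }
  pt <- paired_ttest(maps[cond == "abstinence", ], maps[cond == "satiety", ],
                     grid = grid)
  cl <- extract_clusters(pt, p_thresh = 0.005, min_extent = 20)
  if (length(cl)) {
    tab <- cbind(network = net, cluster_table(cl))
    cluster_rows <- rbind(cluster_rows, tab)
    roi <- roi_from_cluster(cl[[1]], pt, grid, name = paste0(net, "_peak"))
    if (!is.null(roi)) rois[[net]] <- roi
  }
}
if (!is.null(cluster_rows)) {
  write.table(cluster_rows, "results/paired_clusters.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%d paired-t clusters written; ROIs defined for: %s\n",
              nrow(cluster_rows), paste(names(rois), collapse = ", ")))
}
jsonlite::write_json(
  lapply(rois, function(r) list(name = r$name, center_voxel = r$center_voxel,
                                n_voxels = length(r$member_voxels))),
  "results/rois.json", auto_unbox = TRUE, pretty = TRUE)
saveRDS(rois, "scratch/rois.rds")
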