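# Shared fixtures, all generated in code.

# A small trajectory spec that keeps per-test runtimes low.
tiny_traj_spec <- function(...) {
  trajectory_spec(n_lipids_per_leaflet = 16, duration = 10,
                  frame_interval = 0.5, ...)
}

# Hand-built single frame: two perfect phosphate planes and a dye rod,
# no generator involved (independent of synth).
flat_frame <- function(thickness = 40, n_per_leaflet = 4,
                       dye = rbind(c(0, 0, 14), c(0, 0, 12), c(0, 0, 10)),
                       dye_names = c("N2", "N3", "C23")) {
  p_top <- cbind(seq_len(n_per_leaflet) * 5, 0, thickness / 2)
  p_bot <- cbind(seq_len(n_per_leaflet) * 5, 0, -thickness / 2)
  coords <- rbind(p_top, p_bot, dye)
  np <- 2 * n_per_leaflet
  structure(list(time = 0, coordinates = coords,
                 atom_names = c(rep("P", np), dye_names),
                 p_atom_indices = seq_len(np),
                 dye_atom_indices = np + seq_len(nrow(dye)),
                 dye_heavy_indices = np + seq_len(nrow(dye)),
                 box = NULL),
            class = "BilayerFrame")
}

# Jaccard index of two pixel-index sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
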