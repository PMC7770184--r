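# small cohort configurations used across test files
tiny_config <- function(..., seed = 42L) {
  synth_config(n_controls = 6L, n_patients = 6L, n_rois = 8L,
               n_timepoints = 60L, seed = seed, ...)
}

# directly-constructed (oracle) three-group targets for a planted-edge
# config, without PSD repair — used to check build_group_targets
oracle_targets <- function(R, base, edges) {
  mk <- function() { m <- matrix(base, R, R); diag(m) <- 1; m }
  tg <- list(NC = mk(), IBSbs = mk(), IBS1st = mk())
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    normal <- if (is.finite(edges$nc_level[k])) edges$nc_level[k] else base
    abn <- normal + ifelse(edges$direction[k] == "increase", 1, -1) * edges$delta[k]
    vals <- switch(edges$state[k],
                   disorder = c(normal, abn, abn),
                   cured = c(normal, abn, normal),
                   activated = c(normal, normal, abn))
    for (g in 1:3) {
      tg[[g]][i, j] <- vals[g]
      tg[[g]][j, i] <- vals[g]
    }
  }
  tg
}
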