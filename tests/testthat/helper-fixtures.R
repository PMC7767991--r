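# Shared fixtures: tiny grids and hand-built cohorts, all constructed in code.

tiny_geom <- function(shape = c(6L, 6L, 6L), vox = 2) {
  centered_geometry(shape, vox)
}

# mask with lesion at the given voxel indices (matrix of 1-based ijk rows,
# or vector of linear indices)
make_mask <- function(idx, geom, subject_id = "s1",
                      compartment = "enhancing") {
  arr <- array(0L, geom$shape)
  if (is.matrix(idx)) arr[idx] <- 1L else arr[idx] <- 1L
  binary_mask(arr, geom, subject_id, compartment)
}

# 4-subject toy cohort (3 recurrence + 1 psp by default) with hand-placed
# lesions, used for exact frequency arithmetic
toy_cohort_4 <- function(geom = tiny_geom()) {
  m1 <- make_mask(rbind(c(2, 2, 2), c(3, 3, 3)), geom, "r1")
  m2 <- make_mask(rbind(c(2, 2, 2), c(4, 4, 4)), geom, "r2")
  m3 <- make_mask(rbind(c(2, 2, 2), c(3, 3, 3), c(4, 4, 4)), geom, "r3")
  m4 <- make_mask(rbind(c(2, 2, 2)), geom, "p1")
  assemble_cohort(list(m1, m2, m3, m4),
                  c("recurrence", "recurrence", "recurrence", "psp"))
}

# independent brute-force oracle for the two-tailed exact test: enumerate all
# tables with the observed margins via the hypergeometric form
# P(k) = choose(r1, k) choose(r2, c1 - k) / choose(n, c1)
# and sum the point probabilities not exceeding the observed one.
fisher_oracle <- function(a, b, c, d, rel_slack = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- pk[ks == a]
  min(sum(pk[pk <= p_obs * (1 + rel_slack)]), 1)
}
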