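# Independent oracles and small scene builders shared across tests.

# Exhaustive-enumeration oracle for the gated assignment problem: minimises
# sum(matched distances) + d_max * (# unmatched points) over every partial
# injective assignment whose pair distances obey the gate. Recursion over
# cloud A rows; feasible because test clouds are tiny (<= 6 points).
oracle_gated_match <- function(A, B, d_max) {
  na <- nrow(A); nb <- nrow(B)
  if (na == 0 || nb == 0)
    return(list(objective = d_max * (na + nb), n_pairs = 0L,
                matched_cost = 0))
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(na), na + seq_len(nb),
                                           drop = FALSE]
  best <- list(objective = d_max * (na + nb), n_pairs = 0L, matched_cost = 0)
  rec <- function(i, used, cost, k) {
    if (i > na) {
      obj <- cost + d_max * ((na - k) + (nb - k))
      if (obj < best$objective - 1e-9)
        best <<- list(objective = obj, n_pairs = k, matched_cost = cost)
      return(invisible())
    }
    rec(i + 1L, used, cost, k)                     # leave point i unmatched
    for (j in which(!used & D[i, ] <= d_max)) {
      used[j] <- TRUE
      rec(i + 1L, used, cost + D[i, j], k + 1L)
      used[j] <- FALSE
    }
    invisible()
  }
  rec(1L, rep(FALSE, nb), 0, 0L)
  best
}

# the objective value achieved by a match_set under the same criterion
match_objective <- function(m) {
  m$total_cost + m$d_max * (length(m$unmatched_a) + length(m$unmatched_b))
}

# double-loop ECDF sup-difference (brute force, no pooling shortcuts)
ks_D_bruteforce <- function(a, b) {
  gap <- 0
  for (t in c(a, b)) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    gap <- max(gap, abs(fa - fb))
  }
  gap
}

# per-label Jaccard of a recovered label mask against the true mask,
# matching each recovered label to the true label it overlaps most
mask_jaccard <- function(recovered, truth) {
  labs <- sort(setdiff(unique(as.vector(recovered)), 0L))
  vapply(labs, function(l) {
    rec <- recovered == l
    over <- truth[rec & truth > 0L]
    if (!length(over)) return(0)
    tl <- as.integer(names(sort(table(over), decreasing = TRUE))[1])
    tr <- truth == tl
    sum(rec & tr) / sum(rec | tr)
  }, numeric(1))
}

# a small single-cell scene; overrides merge into the defaults below
small_scene_params <- function(..., seed = 1L) {
  defaults <- list(shape = c(z = 6L, y = 48L, x = 48L), n_cells = 1L,
                   cell_radius = 14, nucleus_radius = 5,
                   spots_per_cell = 50L, n_channels = 1L, seed = seed)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# per-cell enrichment ratios from n independent single-cell scenes
simulated_ratios <- function(n_cells, r, seed, spots = 50L, noise = 6) {
  vapply(seq_len(n_cells), function(i) {
    sc <- simulate_scene(small_scene_params(
      r = r, if_noise_sd = noise, spots_per_cell = spots,
      seed = seed + i))
    st <- render_stacks(sc, channels = "if")
    enrichment_ratio(st[["if"]], sc$spots$fish_a, sc$geometry,
                     sc$geometry$labels[1])$ratio
  }, numeric(1))
}

# draw a random point cloud in a box, sizes in nm
random_cloud <- function(n, extent = c(2000, 2000, 1200)) {
  cbind(x_nm = runif(n, 0, extent[1]),
        y_nm = runif(n, 0, extent[2]),
        z_nm = runif(n, 0, extent[3]))
}
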