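# Independent oracles and fixture builders used across the suite.

# brute-force maximum pairwise distance, O(n^2), no shortcuts
brute_max_pair <- function(pts) {
  n <- nrow(pts)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# exhaustive concordant/discordant pair counting for the AUC
# (smaller score for a passed stone counts as concordant; ties 0.5)
brute_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == "passed"]
  neg <- scores[outcomes == "not_passed"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p < q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# random 26-connected voxel blob of at most n_max voxels in a cube grid
random_blob_mask <- function(n_max, grid = 14L, spacing = 0.25) {
  occ <- array(FALSE, rep(grid, 3))
  cur <- matrix(rep(ceiling(grid / 2), 3), 1)
  occ[cur] <- TRUE
  n <- 1L
  frontier <- cur
  while (n < n_max) {
    pick <- frontier[sample.int(nrow(frontier), 1), ]
    step <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    nxt <- pmin(pmax(pick + step, 1L), grid)
    if (!occ[nxt[1], nxt[2], nxt[3]]) {
      occ[nxt[1], nxt[2], nxt[3]] <- TRUE
      n <- n + 1L
    }
    frontier <- rbind(frontier, nxt)
  }
  stone_mask(occ, spacing = rep(spacing, 3))
}

# a ct_volume with constant background and explicit voxel values
flat_volume <- function(dims, value = 100, spacing = c(0.25, 0.25, 0.25)) {
  ct_volume(array(value, dims), spacing = spacing)
}

# passage model with an (effectively) constant probability of 1
constant_pass_model <- function() {
  m <- calibrate_from_anchors(anchor_set(c(4, 5), c(0.73, 0.35), "upper"))
  m$intercept <- 700
  m$slope <- -1e-9
  m
}

# four secondary-analysis models for upper stones (user-supplied anchors;
# none are published, so these are test constructions)
secondary_model_set <- function() {
  list(
    width_bone = calibrate_from_anchors(anchor_set(c(4.2, 5), c(0.73, 0.35), "upper")),
    length_bone = calibrate_from_anchors(anchor_set(c(5.5, 7), c(0.73, 0.35), "upper", measure = "length")),
    width_soft = calibrate_from_anchors(anchor_set(c(5.0, 6), c(0.75, 0.40), "upper", window = "soft")),
    length_soft = calibrate_from_anchors(anchor_set(c(6.5, 8.2), c(0.75, 0.42), "upper", measure = "length", window = "soft")))
}
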