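# Shared fixtures, built in code and memoized across test files so the
# expensive ones (a trained toy network) are constructed once per run.

.fixtures <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

tiny_atlas <- function() {
  with_cache("atlas16", generate_toy_atlas(c(16L, 16L, 16L), 4L, seed = 2))
}

# a pet_atlas built by hand from an explicit label array
hand_atlas <- function(labels, names, is_reference = NULL) {
  labels <- array(as.integer(labels), dim(labels))
  ids <- seq_along(names)
  structure(list(
    labels = labels,
    regions = data.frame(id = ids, name = names,
                         is_reference = is_reference %||%
                           names %in% c("pons", "cerebellum"),
                         stringsAsFactors = FALSE),
    affine = diag(4)
  ), class = "pet_atlas")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strongly separable toy cohort + trained scaled-down network
tiny_trained <- function() {
  with_cache("fit16", {
    atl <- tiny_atlas()
    cc <- cohort_config(c(16, 16, 16), 20, prevalence = 0.5,
                        hypo_regions = 1, hyper_regions = 2,
                        effect_size = 0.30, noise_sd = 0.03, seed = 31)
    coh <- generate_cohort(cc, atl)
    nv <- lapply(coh$volumes, normalize_by_reference, atlas = atl)
    cfg <- slicenet_config(c(16, 16, 16), conv_filters = c(4, 8, 8, 8),
                           learning_rate = 1e-3, max_epochs = 5,
                           seed = 7)
    fit <- slicenet(nv, coh$meta$label, cfg,
                    subject_ids = coh$meta$subject_id)
    list(fit = fit, cohort = coh, volumes = nv, atlas = atl)
  })
}

# independent flood-fill component labelling (the oracle for the
# compiled component labeller)
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  a <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- a > 0 & ((connectivity == 26) | (connectivity == 18 & a <= 2) |
                     (connectivity == 6 & a <= 1))
  off <- off[keep, ]
  lab <- array(0L, d)
  nid <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    nid <- nid + 1L
    stack <- list(p)
    lab[p[1], p[2], p[3]] <- nid
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(off))) {
        np <- q + c(off$dx[k], off$dy[k], off$dz[k])
        if (any(np < 1) || any(np > d)) next
        if (mask[np[1], np[2], np[3]] && lab[np[1], np[2], np[3]] == 0L) {
          lab[np[1], np[2], np[3]] <- nid
          stack[[length(stack) + 1L]] <- np
        }
      }
    }
  }
  lab
}

# same-partition check up to label renaming
same_partition <- function(a, b) {
  pairs <- unique(cbind(as.vector(a), as.vector(b)))
  all(table(pairs[, 1]) == 1) && all(table(pairs[, 2]) == 1)
}
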