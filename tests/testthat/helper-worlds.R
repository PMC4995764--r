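# Shared miniature setups used across the test files. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# A structurally faithful but tiny parameter set: 50 resource species over
# 10 patch types, 50 patches of 20 items.
tiny_params <- function(...) {
  forage_params(R = 50, n_patch_types = 10, types_per_patch_type = 5,
                n_patches = 50, items_per_patch = 20, world_area = 250^2,
                N = 10, ...)
}

# A random micro-scenario for scheduler tests: 2-5 solitary foragers with
# random traits in a small item field. Deaths are disabled by generous
# energy and negligible metabolism so the event chains stay unbroken.
random_micro_scenario <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  p <- forage_params(N = n, Z = 0, metabolism_rate = 1e-9,
                     founder_energy = 1e8)
  side <- 60
  n_items <- sample(5:40, 1)
  w <- fixture_world(
    types = tibble::tibble(Q = runif(3, 0.05, 0.3), H = runif(3, 0.5, 2),
                           S = sample(1:4, 3, replace = TRUE)),
    items = tibble::tibble(x = runif(n_items, 20, 40),
                           y = runif(n_items, 20, 40),
                           type = sample(1:3, n_items, replace = TRUE)),
    side = side
  )
  pop <- fixture_population(
    p, x = runif(n, 20, 40), y = runif(n, 20, 40),
    heading = runif(n, 0, 2 * pi),
    traits = list(delta = runif(n, 1, 8), epsilon = runif(n, 0, 1),
                  lambda = runif(n, 0.2, 1), sigma = runif(n, 0, 5),
                  phi = runif(n, 0, 0.2)))
  list(params = p, world = w, population = pop)
}

# Brute-force chronological replay of an engine event log: rebuilds each
# forager's chain of action durations and merges the chains by scanning
# for the globally earliest completion (ties: lower slot first). Returns
# the replayed (start time, slot) sequence.
replay_event_order <- function(events) {
  chains <- split(events$duration, events$slot)
  slots <- as.integer(names(chains))
  nexti <- setNames(rep(1L, length(chains)), names(chains))
  tnow <- setNames(rep(0, length(chains)), names(chains))
  out_t <- numeric(nrow(events))
  out_slot <- integer(nrow(events))
  for (k in seq_len(nrow(events))) {
    # the next decision (log row) happens at the earliest pending start,
    # i.e. for the forager whose previous action completes first; the
    # engine breaks ties by slot
    cand <- which(tnow == min(tnow))
    pick <- cand[which.min(slots[cand])]
    out_t[k] <- tnow[pick]
    out_slot[k] <- slots[pick]
    tnow[pick] <- tnow[pick] + chains[[pick]][nexti[pick]]
    nexti[pick] <- nexti[pick] + 1L
    if (nexti[pick] > length(chains[[pick]])) tnow[pick] <- Inf
  }
  list(t = out_t, slot = out_slot)
}
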