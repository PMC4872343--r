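# Internal helpers shared across modules.

# Stage labels in biological order, taken from a design table. The first
# stage is always the comparison baseline.
stage_levels <- function(design) {
  if (is.factor(design$stage)) levels(design$stage) else unique(design$stage)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# Run an expression under a local RNG state seeded with `seed` (if non-NULL),
# restoring the caller's RNG afterwards. Keeps all package randomness
# reproducible without clobbering the user's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Greedy sample of up to `k` nodes from `pool` that form an independent set
# in the tree given by adjacency list `adj` (named list of neighbor ids).
# With `d2 = TRUE` chosen nodes are additionally pairwise at distance >= 3.
# `blocked` seeds the exclusion zone (a previously chosen set plus its
# neighborhood is avoided). Order is randomized, so call under a seed.
greedy_tree_sample <- function(pool, adj, k, d2 = FALSE, blocked = character()) {
  if (k <= 0 || length(pool) == 0) return(character())
  if (length(blocked)) {
    blocked <- unique(c(blocked, unlist(adj[intersect(blocked, names(adj))], use.names = FALSE)))
  }
  pool <- sample(pool)
  chosen <- character(length(pool))
  n_chosen <- 0L
  blocked_env <- new.env(hash = TRUE, size = 4L * length(pool))
  for (b in blocked) assign(b, TRUE, envir = blocked_env)
  for (s in pool) {
    if (n_chosen >= k) break
    if (exists(s, envir = blocked_env, inherits = FALSE)) next
    n_chosen <- n_chosen + 1L
    chosen[n_chosen] <- s
    nb <- adj[[s]] %||% character()
    blk <- c(s, nb)
    if (d2 && length(nb)) {
      blk <- c(blk, unlist(adj[intersect(nb, names(adj))], use.names = FALSE))
    }
    for (b in blk) assign(b, TRUE, envir = blocked_env)
  }
  chosen[seq_len(n_chosen)]
}

roman_pathways <- function() c("i", "ii", "iii", "iv", "v", "vi", "vii")

pathway_levels <- function() c(roman_pathways(), "none")
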