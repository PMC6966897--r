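# Shared, lazily built objects reused across test files (built once per run).
.shared_cache <- new.env(parent = emptyenv())

shared <- function(name, build) {
  if (is.null(.shared_cache[[name]])) .shared_cache[[name]] <- build()
  .shared_cache[[name]]
}

desk_params <- function() polymer_params()

# 60-bin null ensembles: one for building nulls, an independent one as
# "measured" self-null input.
ens60a <- function() {
  shared("ens60a", function() {
    sample_null_ensemble(desk_params(), 60, 1200, seed = 2)
  })
}
ens60b <- function() {
  shared("ens60b", function() {
    sample_null_ensemble(desk_params(), 60, 1200, seed = 12)
  })
}
cnull60 <- function() {
  shared("cnull60", function() build_contact_null(ens60a(), n_outer = 2000, seed = 3))
}
locus60 <- function() locus_spec("chrS", 0, 60 * 5000)

# small complete fixture world
fx_small <- function() {
  shared("fx_small", function() {
    make_fixture(
      n_bins = 60, M = 6, n_cells = 60, folds_per_cell = 5, seed = 11
    )
  })
}

# the desk-scale fixture (used by acceptance tests)
fx_desk <- function() shared("fx_desk", function() make_fixture(seed = 7))

# assemble a chromatin_ensemble-like object from a coordinate array
fake_ensemble <- function(coords, params = desk_params(), lw = NULL) {
  structure(
    list(
      coords = coords, log_weights = lw %||% rep(0, dim(coords)[3]),
      params = params, kind = "null", constraint_set = NULL,
      confinement_radius = NA_real_, seed = NA, diagnostics = list()
    ),
    class = "chromatin_ensemble"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent exhaustive clique enumeration (growth over sorted vertex sets);
# returns list(threebody = k x 3 matrix, maximal = list of member vectors)
oracle_cliques <- function(xyz, threshold, min_sep) {
  n <- nrow(xyz)
  D <- as.matrix(dist(xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  adj <- D <= threshold & sep >= min_sep
  diag(adj) <- FALSE
  res <- list()
  grow <- function(set, cand) {
    for (v in cand) {
      if (all(adj[set, v])) {
        ns <- c(set, v)
        if (length(ns) >= 3) res[[length(res) + 1]] <<- ns
        grow(ns, cand[cand > v])
      }
    }
  }
  if (n >= 3) for (a in seq_len(n - 2)) grow(a, (a + 1):n)
  three <- if (length(res)) {
    do.call(rbind, res[lengths(res) == 3])
  } else {
    matrix(integer(0), ncol = 3)
  }
  maximal <- Filter(function(s) {
    others <- setdiff(seq_len(n), s)
    !any(vapply(others, function(v) all(adj[s, v]), logical(1)))
  }, res)
  list(threebody = three, maximal = maximal)
}
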