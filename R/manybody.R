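#' Enumerate exact 3-body complexes in one conformation
#'
#' A 3-body interaction is a triplet of bins whose three pairwise Euclidean
#' distances are all within the contact threshold (a 3-clique of the contact
#' graph); triplets need not be maximal and may sit inside larger complexes.
#' Pairs closer than `min_separation` bins along the genome are excluded —
#' bonded-neighbour triangles are ubiquitous and uninformative.
#'
#' @param conf A conformation (`n x 3` matrix or `conformation` object).
#' @param params [polymer_params()] supplying the contact threshold.
#' @param min_separation Minimum genomic separation in bins (default 2).
#' @return Tibble: members `b1 < b2 < b3`, `size`, `maximal`, genomic
#'   `principal_span` / `minor_span` (bp) and the principal anchors.
#' @export
enumerate_3body <- function(conf, params, min_separation = 2) {
  xyz <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  tri <- triangles_cpp(xyz, params$contact_threshold, as.integer(min_separation))
  if (nrow(tri) == 0) {
    return(tibble::tibble(
      b1 = integer(), b2 = integer(), b3 = integer(), size = integer(),
      maximal = logical(), principal_span = numeric(), minor_span = numeric(),
      anchor1 = integer(), anchor2 = integer()
    ))
  }
  span31 <- tri[, 3] - tri[, 1]
  span21 <- tri[, 2] - tri[, 1]
  span32 <- tri[, 3] - tri[, 2]
  tibble::tibble(
    b1 = tri[, 1], b2 = tri[, 2], b3 = tri[, 3], size = 3L, maximal = FALSE,
    principal_span = span31 * params$bead_bp,
    minor_span = pmin(span21, span32) * params$bead_bp,
    anchor1 = tri[, 1], anchor2 = tri[, 3]
  )
}

# anchors: member pair with the largest genomic span; lexicographic tie-break
# is automatic because members are sorted and the span is |i - j|.
clique_annotation <- function(members, bead_bp) {
  members <- sort(members)
  spans <- outer(members, members, function(a, b) abs(a - b))
  spans <- spans[upper.tri(spans)]
  pairs <- which(upper.tri(diag(length(members))), arr.ind = TRUE)
  best <- which.max(spans)
  list(
    principal_span = max(spans) * bead_bp,
    minor_span = min(spans) * bead_bp,
    anchor1 = members[pairs[best, 1]],
    anchor2 = members[pairs[best, 2]]
  )
}

#' Enumerate maximal many-body complexes in one conformation
#'
#' Maximal cliques (size >= 3) of the thresholded contact graph, found with
#' igraph's maximal-clique enumeration; each complex is annotated with its
#' principal (longest) and minor (shortest) genomic loop spans and the
#' anchor pair realizing the principal span.
#'
#' @inheritParams enumerate_3body
#' @return Tibble with list-column `members`, `size`, `maximal`,
#'   `principal_span`, `minor_span`, `anchor1`, `anchor2`.
#' @export
enumerate_maximal <- function(conf, params, min_separation = 2) {
  xyz <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  n <- nrow(xyz)
  edges <- contact_edges_cpp(
    xyz, params$contact_threshold, as.integer(min_separation)
  )
  empty <- tibble::tibble(
    members = list(), size = integer(), maximal = logical(),
    principal_span = numeric(), minor_span = numeric(),
    anchor1 = integer(), anchor2 = integer()
  )
  if (nrow(edges) == 0) return(empty)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  cl <- igraph::max_cliques(g, min = 3)
  if (length(cl) == 0) return(empty)
  rows <- lapply(cl, function(v) {
    members <- sort(as.integer(v))
    k <- length(members)
    ann <- clique_annotation(members, params$bead_bp)
    tibble::tibble(
      members = list(members), size = k, maximal = TRUE,
      principal_span = ann$principal_span, minor_span = ann$minor_span,
      anchor1 = ann$anchor1, anchor2 = ann$anchor2
    )
  })
  dplyr::bind_rows(rows)
}

size_class <- function(k) ifelse(k >= 6, "6+", as.character(k))

# Tally complex signatures across an ensemble. 3-bodies are keyed by their
# exact member triplet; maximal complexes by principal anchor pair plus size
# class (exact member multisets are too sparse to tally). Conformations are
# treated as equally weighted samples. Signatures are integer-coded into a
# dense count vector so desk-scale ensembles (millions of triangle
# occurrences) tally in seconds.
tally_manybody <- function(ensemble, mode = c("3body", "maximal"), params,
                           min_separation = 2) {
  mode <- match.arg(mode)
  n_conf <- n_conformations(ensemble)
  n <- dim(ensemble$coords)[1]
  empty <- tibble::tibble(
    signature = character(), count = integer(), frequency = numeric(),
    principal_bins = integer(), minor_bins = integer(),
    size_class = character(), anchor1 = integer(), anchor2 = integer(),
    stratum = character()
  )
  if (mode == "3body") {
    if (n > 270) {
      abort("3-body tallying supports up to 270 bins; raise min_separation or coarsen the locus.")
    }
    cnt <- integer(n^3)
    for (c in seq_len(n_conf)) {
      tri <- triangles_cpp(
        ensemble$coords[, , c], params$contact_threshold,
        as.integer(min_separation)
      )
      if (nrow(tri) == 0) next
      id <- ((tri[, 1] - 1L) * n + (tri[, 2] - 1L)) * n + tri[, 3]
      cnt[id] <- cnt[id] + 1L
    }
    ids <- which(cnt > 0L)
    if (length(ids) == 0) return(list(tally = empty, n_conf = n_conf, mode = mode))
    b3 <- (ids - 1L) %% n + 1L
    r <- (ids - 1L) %/% n
    b2 <- r %% n + 1L
    b1 <- r %/% n + 1L
    tal <- tibble::tibble(
      signature = paste(b1, b2, b3, sep = "_"), count = cnt[ids],
      principal_bins = b3 - b1, minor_bins = pmin(b2 - b1, b3 - b2),
      size_class = "3", anchor1 = b1, anchor2 = b3
    )
  } else {
    cnt <- integer(n * n * 4L)
    for (c in seq_len(n_conf)) {
      edges <- contact_edges_cpp(
        ensemble$coords[, , c], params$contact_threshold,
        as.integer(min_separation)
      )
      if (nrow(edges) == 0) next
      g <- igraph::make_empty_graph(n = n, directed = FALSE)
      g <- igraph::add_edges(g, t(edges))
      cl <- igraph::max_cliques(g, min = 3)
      if (length(cl) == 0) next
      rng <- vapply(cl, function(v) c(min(v), max(v)), numeric(2))
      kcls <- pmin(lengths(cl), 6L) - 3L # 0..3 for sizes 3,4,5,6+
      id <- unique(((rng[1, ] - 1L) * n + (rng[2, ] - 1L)) * 4L + kcls + 1L)
      cnt[id] <- cnt[id] + 1L
    }
    ids <- which(cnt > 0L)
    if (length(ids) == 0) return(list(tally = empty, n_conf = n_conf, mode = mode))
    kcls <- (ids - 1L) %% 4L
    r <- (ids - 1L) %/% 4L
    a2 <- r %% n + 1L
    a1 <- r %/% n + 1L
    size_lab <- c("3", "4", "5", "6+")[kcls + 1L]
    tal <- tibble::tibble(
      signature = paste(a1, a2, size_lab, sep = "_"), count = cnt[ids],
      principal_bins = a2 - a1, minor_bins = NA_integer_,
      size_class = size_lab, anchor1 = a1, anchor2 = a2
    )
  }
  tal$frequency <- tal$count / n_conf
  tal$stratum <- if (mode == "3body") {
    paste0("p", tal$principal_bins, "_m", tal$minor_bins)
  } else {
    paste0("k", tal$size_class, "_p", tal$principal_bins)
  }
  list(tally = tal, n_conf = n_conf, mode = mode)
}

#' Stratified bootstrap null over many-body interaction frequencies
#'
#' Tallies every complex in a uniform random ensemble, then bootstraps the
#' conformations (1000 replicates by default, the reference setting) to
#' obtain, per stratum, a null distribution of per-complex frequencies.
#' Strata are (principal span, minor span) for 3-bodies and (clique size
#' class, principal span) for maximal complexes, at one-bin (5-KB)
#' granularity. Because a complex occurs at most once per conformation, its
#' bootstrap frequency distribution depends only on its occurrence count, so
#' replicates are drawn per distinct count (`Binomial(n, c/n)/n`) and pooled
#' with class multiplicities — distributionally identical to resampling every
#' complex, at a fraction of the cost.
#'
#' @param null_ensemble A `chromatin_ensemble` of random folds (paper scale
#'   75,000 polymers; desk default ~2000).
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param mode `"3body"` or `"maximal"`.
#' @param params [polymer_params()].
#' @param min_separation Minimum genomic separation in bins (default 2).
#' @param seed RNG seed.
#' @return A `manybody_null` with per-stratum pooled replicate values.
#' @export
build_manybody_null <- function(null_ensemble, n_replicates = 1000,
                                mode = c("3body", "maximal"),
                                params = NULL, min_separation = 2, seed = 1) {
  mode <- match.arg(mode)
  params <- params %||% null_ensemble$params
  withr::local_seed(seed)
  tl <- tally_manybody(null_ensemble, mode, params, min_separation)
  n <- tl$n_conf
  strata <- list()
  if (nrow(tl$tally) > 0) {
    for (st in split(tl$tally, tl$tally$stratum)) {
      classes <- table(st$count)
      vals <- numeric(0)
      wts <- numeric(0)
      for (ci in seq_along(classes)) {
        cc <- as.integer(names(classes)[ci])
        reps <- rbinom(n_replicates, n, cc / n) / n
        vals <- c(vals, reps)
        wts <- c(wts, rep(as.numeric(classes[ci]), n_replicates))
      }
      o <- order(vals)
      strata[[st$stratum[1]]] <- list(
        values = vals[o], weights = wts[o], total = sum(wts)
      )
    }
  }
  structure(
    list(
      strata = strata, n_conf = n, n_replicates = n_replicates, mode = mode,
      min_separation = min_separation, tally = tl$tally, seed = seed
    ),
    class = "manybody_null"
  )
}

#' @export
print.manybody_null <- function(x, ...) {
  cat(sprintf(
    "<manybody_null> mode %s, %d strata, %d replicates over %d conformations\n",
    x$mode, length(x$strata), x$n_replicates, x$n_conf
  ))
  invisible(x)
}

# add-one weighted exceedance p-value against one or more pooled strata
null_p_value <- function(freq, pools) {
  tot <- 0
  exc <- 0
  for (p in pools) {
    tot <- tot + p$total
    k <- findInterval(freq - 1e-12, p$values)
    exc <- exc + sum(p$weights[seq_len(length(p$values)) > k])
  }
  if (tot == 0) return(NA_real_)
  (1 + exc) / (1 + tot)
}

#' Call specific many-body interactions
#'
#' Tallies complex frequencies in the reconstructed (deconvolved) ensemble
#' and assigns each complex an add-one p-value: the within-stratum weighted
#' proportion of bootstrap null frequencies reaching its frequency.
#' Benjamini-Hochberg FDR is applied across all tested complexes; a complex
#' is *specific* when `q < alpha`. Complexes falling in a stratum absent
#' from the null are compared against strata pooled within +/-2 span bins
#' (reported in the `pooled` column); if no null stratum is found even after
#' pooling, the p-value is set to 1 (conservative).
#'
#' @param ensemble The reconstructed (or any) ensemble to test.
#' @param null A `manybody_null` built with the same mode and separation.
#' @param alpha FDR threshold (default 0.05).
#' @param params [polymer_params()]; defaults to the ensemble's.
#' @return A `manybody_calls` tibble.
#' @export
call_specific_manybodies <- function(ensemble, null, alpha = 0.05,
                                     params = NULL) {
  params <- params %||% ensemble$params
  tl <- tally_manybody(ensemble, null$mode, params, null$min_separation)
  tal <- tl$tally
  if (nrow(tal) == 0) {
    return(structure(
      tibble::tibble(
        signature = character(), size_class = character(),
        anchor1 = integer(), anchor2 = integer(),
        principal_span = numeric(), minor_span = numeric(),
        frequency = numeric(), p_value = numeric(), q_value = numeric(),
        specific = logical(), pooled = logical()
      ),
      alpha = alpha, mode = null$mode,
      class = c("manybody_calls", "tbl_df", "tbl", "data.frame")
    ))
  }
  p <- numeric(nrow(tal))
  pooled <- logical(nrow(tal))
  by_stratum <- split(seq_len(nrow(tal)), tal$stratum)
  for (key in names(by_stratum)) {
    rows <- by_stratum[[key]]
    ns <- null$strata[[key]]
    if (!is.null(ns)) {
      # suffix weight sums over the sorted null values: weight at rank > k
      sfx <- c(rev(cumsum(rev(ns$weights))), 0)
      k <- findInterval(tal$frequency[rows] - 1e-12, ns$values)
      p[rows] <- (1 + sfx[k + 1]) / (1 + ns$total)
    } else {
      pooled[rows] <- TRUE
      for (r in rows) {
        offs <- expand.grid(dp = -2:2, dm = -2:2)
        keys <- if (null$mode == "3body") {
          unique(paste0(
            "p", tal$principal_bins[r] + offs$dp,
            "_m", tal$minor_bins[r] + offs$dm
          ))
        } else {
          unique(paste0(
            "k", tal$size_class[r], "_p", tal$principal_bins[r] + -2:2
          ))
        }
        pools <- null$strata[intersect(keys, names(null$strata))]
        p[r] <- if (length(pools) > 0) {
          null_p_value(tal$frequency[r], pools)
        } else {
          1
        }
      }
    }
  }
  if (any(pooled)) {
    message(sprintf(
      "%d complex(es) fell in strata absent from the null; pooled +/-2 spans.",
      sum(pooled)
    ))
  }
  q <- p.adjust(p, method = "BH")
  out <- tibble::tibble(
    signature = tal$signature, size_class = tal$size_class,
    anchor1 = tal$anchor1, anchor2 = tal$anchor2,
    principal_span = tal$principal_bins * params$bead_bp,
    minor_span = tal$minor_bins * params$bead_bp,
    frequency = tal$frequency, p_value = p, q_value = q,
    specific = q < alpha, pooled = pooled
  )
  structure(out,
    alpha = alpha, mode = null$mode,
    class = c("manybody_calls", class(out))
  )
}

# label category of a bin with priority SE > E > P
bin_category <- function(bin_labels, bins) {
  vapply(bins, function(b) {
    row <- bin_labels[bin_labels$bin == b, ]
    if (nrow(row) == 0) return("none")
    if (row$SE) "SE" else if (row$E) "E" else if (row$P) "P" else "none"
  }, character(1))
}

#' Functional landscape of many-body calls
#'
#' Maps complex members (3-body signatures) onto SE/E/P bin labels and
#' aggregates, separately for specific and non-specific complexes: the
#' fraction with no functional association, the fraction with >= 2
#' super-enhancer members plus a promoter, the fraction with >= 3
#' super-enhancer members, and the label-pair table of principal-loop
#' anchors (categories prioritized SE > E > P).
#'
#' @param calls A `manybody_calls` tibble (3-body mode for member-level
#'   fractions; anchor pairs are computed for any mode).
#' @param annotations An `annotation_track` (or pre-computed [annotate_bins()]
#'   tibble).
#' @param locus Optional [locus_spec()].
#' @return A `landscape_summary` list: `$fractions` and `$anchor_pairs`
#'   tibbles.
#' @export
functional_landscape <- function(calls, annotations, locus = NULL) {
  labels <- if (is.data.frame(annotations) && "bin" %in% names(annotations)) {
    annotations
  } else {
    annotate_bins(annotations, locus)
  }
  calls <- tibble::as_tibble(as.data.frame(calls))
  members_of <- function(sig, size_class) {
    parts <- strsplit(sig, "_")[[1]]
    as.integer(parts[seq_len(if (size_class == "3" &&
      length(parts) == 3) 3 else 2)])
  }
  per_complex <- purrr::map2_dfr(
    calls$signature, calls$size_class,
    function(sig, sc) {
      mem <- members_of(sig, sc)
      cats <- bin_category(labels, mem)
      n_se <- sum(cats == "SE")
      tibble::tibble(
        none = all(cats == "none"),
        ge2_se_with_p = n_se >= 2 && any(cats == "P"),
        ge3_se = n_se >= 3
      )
    }
  )
  dat <- dplyr::bind_cols(calls, per_complex)
  dat$group <- ifelse(dat$specific, "specific", "non-specific")
  fractions <- dplyr::summarise(
    dplyr::group_by(dat, .data$group),
    n = dplyr::n(),
    no_functional = mean(.data$none),
    ge2_SE_with_P = mean(.data$ge2_se_with_p),
    ge3_SE = mean(.data$ge3_se),
    .groups = "drop"
  )
  dat$cat1 <- bin_category(labels, dat$anchor1)
  dat$cat2 <- bin_category(labels, dat$anchor2)
  pair_lab <- purrr::map2_chr(dat$cat1, dat$cat2, function(a, b) {
    paste(sort(c(a, b)), collapse = "-")
  })
  anchor_pairs <- dplyr::count(
    tibble::tibble(group = dat$group, pair = pair_lab),
    .data$group, .data$pair
  )
  anchor_pairs <- dplyr::mutate(
    dplyr::group_by(anchor_pairs, .data$group),
    proportion = .data$n / sum(.data$n)
  )
  structure(
    list(fractions = fractions, anchor_pairs = dplyr::ungroup(anchor_pairs)),
    class = "landscape_summary"
  )
}

#' Cluster coverage fraction of complexes
#'
#' Coverage of a complex is the fraction of proximity clusters (SPRITE-like
#' co-capture records) containing all of its members — or, for principal
#' loops, both anchors.
#'
#' @param calls A `manybody_calls` tibble.
#' @param clusters List of integer vectors of co-captured bins.
#' @param anchors_only Use the two principal anchors instead of all members.
#' @return `calls` with a `coverage` column.
#' @export
coverage_fraction <- function(calls, clusters, anchors_only = FALSE) {
  if (length(clusters) == 0) abort("No clusters supplied.")
  calls <- tibble::as_tibble(as.data.frame(calls))
  cov <- vapply(seq_len(nrow(calls)), function(r) {
    need <- if (anchors_only || calls$size_class[r] != "3") {
      c(calls$anchor1[r], calls$anchor2[r])
    } else {
      as.integer(strsplit(calls$signature[r], "_")[[1]])
    }
    mean(vapply(clusters, function(cl) all(need %in% cl), logical(1)))
  }, numeric(1))
  calls$coverage <- cov
  calls
}

#' Permutation test for specific-vs-non-specific cluster coverage
#'
#' Within each genomic-span stratum, compares the median coverage of
#' specific and non-specific complexes; the observed statistic is the
#' proportion of strata where the specific median exceeds the non-specific
#' one. Specific labels are randomly permuted across complexes (1000
#' replicates by default) and the add-one p-value is the fraction of
#' replicates reaching the observed proportion.
#'
#' @param calls Output of [coverage_fraction()] (needs `coverage`,
#'   `specific`, `principal_span`, and `minor_span` for 3-body mode).
#' @param n_permutations Label permutations (default 1000).
#' @param seed RNG seed.
#' @param by_minor Also stratify by minor span (3-body convention).
#' @return List: `observed_proportion`, `p_value`, `medians` tibble.
#' @export
coverage_permutation_test <- function(calls, n_permutations = 1000, seed = 1,
                                      by_minor = NULL) {
  withr::local_seed(seed)
  calls <- tibble::as_tibble(as.data.frame(calls))
  by_minor <- by_minor %||% all(calls$size_class == "3")
  strat <- if (by_minor) {
    paste(calls$principal_span, calls$minor_span)
  } else {
    as.character(calls$principal_span)
  }
  prop_exceed <- function(spec) {
    meds <- tapply(seq_along(spec), strat, function(idx) {
      s <- spec[idx]
      if (!any(s) || all(s)) return(NA_real_)
      as.numeric(
        median(calls$coverage[idx][s]) > median(calls$coverage[idx][!s])
      )
    })
    mean(unlist(meds), na.rm = TRUE)
  }
  obs <- prop_exceed(calls$specific)
  perms <- vapply(seq_len(n_permutations), function(r) {
    prop_exceed(sample(calls$specific))
  }, numeric(1))
  meds <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(
        stratum = strat, specific = calls$specific,
        coverage = calls$coverage
      ),
      .data$stratum, .data$specific
    ),
    median_coverage = median(.data$coverage), .groups = "drop"
  )
  list(
    observed_proportion = obs,
    p_value = (1 + sum(perms >= obs, na.rm = TRUE)) / (1 + n_permutations),
    medians = meds, n_permutations = n_permutations
  )
}

#' Principal-loop anchor heatmap
#'
#' Entry `(i, j)` is the fraction of conformations in which `(i, j)` is the
#' principal-loop anchor pair of a maximal complex of the requested size
#' class, aggregated over the ensemble.
#'
#' @param ensemble A `chromatin_ensemble` or `reconstructed_ensemble`.
#' @param k Size class: 3, 4, 5 or `"6+"`.
#' @param params [polymer_params()]; defaults to the ensemble's.
#' @param min_separation Minimum genomic separation (bins).
#' @return Symmetric `n x n` matrix.
#' @export
principal_loop_heatmap <- function(ensemble, k, params = NULL,
                                   min_separation = 2) {
  params <- params %||% ensemble$params
  k <- as.character(k)
  stopifnot(k %in% c("3", "4", "5", "6+"))
  n_conf <- n_conformations(ensemble)
  n <- dim(ensemble$coords)[1]
  out <- matrix(0, n, n)
  for (c in seq_len(n_conf)) {
    tb <- enumerate_maximal(ensemble$coords[, , c], params, min_separation)
    if (nrow(tb) == 0) next
    tb <- tb[size_class(tb$size) == k, , drop = FALSE]
    if (nrow(tb) == 0) next
    anchors <- unique(cbind(tb$anchor1, tb$anchor2))
    out[anchors] <- out[anchors] + 1
  }
  out <- out / n_conf
  out + t(out) - diag(diag(out))
}
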