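# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a ring-labeling Monte Carlo experiment
#'
#' Models an oligomeric ring (the 13-fold gamma-tubulin ring by default) in
#' which each position is stochastically labeled with a donor or an acceptor
#' fluorophore, each fluorophore matures (becomes fluorescent) with its own
#' probability, and FRET pairs are counted among fluorescent molecules
#' closer than the FRET radius.
#'
#' Geometry: positions sit on a circle and pairwise distances are exact
#' chords, `d = D * sin(pi * k / n)` for `k` steps around the ring. The ring
#' size is given either as `diameter_nm` (default 25) or as
#' `adjacent_spacing_nm` (e.g. 6.15 nm for a microtubule-lattice-like
#' spacing), which fixes `D = spacing / sin(pi / n)`.
#'
#' Labeling: `n_donor = NULL` gives i.i.d. Bernoulli labeling with donor
#' probability `p_donor`; an integer `n_donor` places exactly that many
#' donors uniformly at random (fixed-count labeling, used for abundance
#' scans).
#'
#' Counting modes: `"pair_count"` counts every fluorescent donor-acceptor
#' pair within the radius (multiple acceptors per donor all count);
#' `"donor_count"` counts donors having at least one fluorescent acceptor
#' within the radius; `"matching"` counts the size of a maximum bipartite
#' matching between fluorescent donors and acceptors on the within-radius
#' graph (a saturating rule: each acceptor can serve only one donor).
#'
#' @param n_positions number of molecules on the ring (>= 2; default 13).
#' @param diameter_nm ring diameter in nm (default 25).
#' @param adjacent_spacing_nm alternative geometry input: distance between
#'   adjacent positions; overrides `diameter_nm` when given.
#' @param fret_radius_nm maximum separation for a FRET pair (default 10).
#' @param p_donor Bernoulli donor probability (default 0.5).
#' @param n_donor exact donor count for fixed-count labeling, or `NULL`.
#' @param maturation_donor,maturation_acceptor per-fluorophore maturation
#'   probabilities in `[0, 1]`.
#' @param counting_mode one of `"pair_count"`, `"donor_count"`, `"matching"`.
#' @param replicates Monte Carlo replicates (default 10000).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `ring_config`.
#' @export
ring_config <- function(n_positions = 13, diameter_nm = 25,
                        adjacent_spacing_nm = NULL, fret_radius_nm = 10,
                        p_donor = 0.5, n_donor = NULL,
                        maturation_donor = 1, maturation_acceptor = 1,
                        counting_mode = c("pair_count", "donor_count", "matching"),
                        replicates = 10000, seed = NULL) {
  counting_mode <- match.arg(counting_mode)
  if (n_positions < 2) abort("Need at least 2 ring positions.",
    class = "fretcal_input_error")
  stopifnot(fret_radius_nm > 0, replicates >= 1,
            maturation_donor >= 0, maturation_donor <= 1,
            maturation_acceptor >= 0, maturation_acceptor <= 1,
            p_donor >= 0, p_donor <= 1)
  if (!is.null(n_donor) && (n_donor < 0 || n_donor > n_positions)) {
    abort(sprintf("n_donor must be in 0..%d.", n_positions),
      class = "fretcal_input_error")
  }
  structure(
    list(n_positions = as.integer(n_positions), diameter_nm = diameter_nm,
         adjacent_spacing_nm = adjacent_spacing_nm,
         fret_radius_nm = fret_radius_nm, p_donor = p_donor,
         n_donor = if (is.null(n_donor)) NULL else as.integer(n_donor),
         maturation_donor = maturation_donor,
         maturation_acceptor = maturation_acceptor,
         counting_mode = counting_mode, replicates = as.integer(replicates),
         seed = seed),
    class = "ring_config"
  )
}

#' Pairwise distances between positions on a circular ring
#'
#' `d(i, j) = D * sin(pi * k / n)` with `k` the shorter arc step count;
#' this is the exact chord length between ring positions.
#'
#' @inheritParams ring_config
#' @return A symmetric `n x n` matrix of distances in nm, zero diagonal.
#' @examples
#' d <- ring_distances(13, diameter_nm = 25)
#' d[1, 2]  # adjacent chord, ~5.98 nm
#' @export
ring_distances <- function(n_positions, diameter_nm = 25,
                           adjacent_spacing_nm = NULL) {
  if (n_positions < 2) abort("Need at least 2 ring positions.",
    class = "fretcal_input_error")
  n <- as.integer(n_positions)
  D <- if (!is.null(adjacent_spacing_nm)) {
    adjacent_spacing_nm / sin(pi / n)
  } else diameter_nm
  i <- matrix(seq_len(n) - 1L, n, n)
  k <- abs(i - t(i))
  k <- pmin(k, n - k)
  D * sin(pi * k / n)
}

#' Draw donor/acceptor labelings for a ring
#'
#' @param config a [ring_config()].
#' @param replicates number of labelings to draw (default from the config).
#' @return A logical matrix `replicates x n_positions`; `TRUE` marks a
#'   donor. Uses the current RNG state (seed the caller, or use
#'   [simulate_ring()] which seeds from the config).
#' @export
assign_labels <- function(config, replicates = config$replicates) {
  n <- config$n_positions
  if (is.null(config$n_donor)) {
    matrix(runif(replicates * n) < config$p_donor, replicates, n)
  } else {
    g <- config$n_donor
    out <- matrix(FALSE, replicates, n)
    if (g > 0) {
      for (r in seq_len(replicates)) out[r, sample.int(n, g)] <- TRUE
    }
    out
  }
}

#' Apply stochastic chromophore maturation to a labeling
#'
#' Each donor is fluorescent with probability `maturation_donor`, each
#' acceptor with probability `maturation_acceptor`, independently.
#'
#' @param labels logical matrix (or vector) from [assign_labels()].
#' @param config a [ring_config()].
#' @return A logical matrix of the same shape; `TRUE` marks a fluorescent
#'   molecule.
#' @export
apply_maturation <- function(labels, config) {
  vec <- is.null(dim(labels))
  if (vec) labels <- matrix(labels, nrow = 1)
  u <- matrix(runif(length(labels)), nrow(labels), ncol(labels))
  fluor <- (labels & u < config$maturation_donor) |
    (!labels & u < config$maturation_acceptor)
  if (vec) fluor[1, ] else fluor
}

# maximum bipartite matching by augmenting paths (Kuhn's algorithm);
# adj: list over donors of acceptor indices
max_bipartite_matching <- function(adj, n_acceptors) {
  match_a <- integer(n_acceptors) # acceptor -> donor (0 = free)
  try_augment <- function(d, visited) {
    for (a in adj[[d]]) {
      if (!visited[a]) {
        visited[a] <- TRUE
        if (match_a[a] == 0L || Recall(match_a[a], visited)) {
          match_a[a] <<- d
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (d in seq_along(adj)) {
    if (try_augment(d, logical(n_acceptors))) size <- size + 1L
  }
  size
}

#' Count FRET pairs in one or many ring configurations
#'
#' @param labels logical vector (one ring) or matrix (rings in rows);
#'   `TRUE` = donor.
#' @param fluorescence logical vector/matrix of the same shape; `TRUE` =
#'   fluorescent.
#' @param distances pairwise distance matrix from [ring_distances()].
#' @param fret_radius_nm pairing radius in nm.
#' @param counting_mode see [ring_config()].
#' @return Integer count (or vector of counts, one per row).
#' @export
count_fret_pairs <- function(labels, fluorescence, distances,
                             fret_radius_nm = 10,
                             counting_mode = c("pair_count", "donor_count",
                                               "matching")) {
  counting_mode <- match.arg(counting_mode)
  vec <- is.null(dim(labels))
  if (vec) {
    labels <- matrix(labels, nrow = 1)
    fluorescence <- matrix(fluorescence, nrow = 1)
  }
  n <- ncol(labels)
  stopifnot(ncol(fluorescence) == n, nrow(fluorescence) == nrow(labels),
            nrow(distances) == n)
  within <- distances <= fret_radius_nm & upper.tri(distances)
  pairs <- which(within, arr.ind = TRUE)
  dF <- labels & fluorescence
  aF <- (!labels) & fluorescence
  counts <- switch(counting_mode,
    pair_count = {
      cnt <- numeric(nrow(labels))
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        cnt <- cnt + (dF[, i] & aF[, j]) + (aF[, i] & dF[, j])
      }
      cnt
    },
    donor_count = {
      adj_full <- distances <= fret_radius_nm
      diag(adj_full) <- FALSE
      # for each position: does it see >= 1 fluorescent acceptor?
      has_acc <- aF %*% adj_full > 0
      rowSums(dF & has_acc)
    },
    matching = {
      adj_full <- distances <= fret_radius_nm
      diag(adj_full) <- FALSE
      vapply(seq_len(nrow(labels)), function(r) {
        dn <- which(dF[r, ]); ac <- which(aF[r, ])
        if (length(dn) == 0 || length(ac) == 0) return(0L)
        adj <- lapply(dn, function(i) which(adj_full[i, ac]))
        max_bipartite_matching(adj, length(ac))
      }, integer(1))
    }
  )
  if (vec) as.integer(counts[1]) else as.integer(counts)
}

ring_summary <- function(counts, config) {
  reps <- length(counts)
  tab <- table(factor(counts, levels = 0:max(max(counts), 0)))
  structure(
    list(
      config = config,
      counts = as.integer(counts),
      histogram = tibble(
        pairs = as.integer(names(tab)),
        probability = as.numeric(tab) / reps
      ),
      mean = mean(counts),
      se = if (reps > 1) sd(counts) / sqrt(reps) else 0
    ),
    class = "ring_result"
  )
}

#' Simulate the distribution of FRET-pair counts on a labeled ring
#'
#' Draws `replicates` independent labelings, applies maturation, counts
#' FRET pairs, and summarizes the resulting distribution. Reproducible for
#' a given config (including seed).
#'
#' @param config a [ring_config()].
#' @return An object of class `ring_result` with fields `histogram`
#'   (tibble: `pairs`, `probability`), `mean`, `se`, `counts` and `config`.
#' @examples
#' res <- simulate_ring(ring_config(replicates = 2000, seed = 1))
#' res$mean  # ~6.5 for unbiased labeling at full maturation
#' @export
simulate_ring <- function(config) {
  stopifnot(inherits(config, "ring_config"))
  d <- ring_distances(config$n_positions, config$diameter_nm,
                      config$adjacent_spacing_nm)
  with_local_seed(config$seed, {
    labels <- assign_labels(config)
    fluor <- apply_maturation(labels, config)
    counts <- count_fret_pairs(labels, fluor, d, config$fret_radius_nm,
                               config$counting_mode)
    ring_summary(counts, config)
  })
}

#' @export
print.ring_result <- function(x, ...) {
  cat(sprintf(
    "<ring_result: %s, %d reps: mean pairs = %.3f +/- %.3f>\n",
    x$config$counting_mode, x$config$replicates, x$mean, x$se))
  invisible(x)
}

#' @method tidy ring_result
#' @export
tidy.ring_result <- function(x, ...) x$histogram

#' @method glance ring_result
#' @export
glance.ring_result <- function(x, ...) {
  tibble(mean_pairs = x$mean, se = x$se, replicates = x$config$replicates,
         counting_mode = x$config$counting_mode)
}

#' @method autoplot ring_result
#' @export
autoplot.ring_result <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$pairs, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "FRET pairs per ring", y = "Probability") +
    ggplot2::theme_minimal()
}

#' Scan donor abundance on the ring and locate the FRET optimum
#'
#' Runs a fixed-count simulation for each donor count `g`, reports the mean
#' FRET pairs with its Monte Carlo standard error, and summarizes the
#' maximizing set: all `g` whose mean lies within one standard error (of
#' the difference) of the best mean, with the midpoint reported for ties.
#'
#' When the two fluorophores have equal maturation probabilities and the
#' counting mode is symmetric under a donor/acceptor swap (`pair_count`,
#' `matching`), the scan couples `g` and `n - g` antithetically by
#' complementing the same label draws, which makes the exact exchange
#' symmetry of the means hold exactly in the simulation as well (a standard
#' common-random-numbers variance-reduction device for comparisons across
#' scan conditions).
#'
#' @param config a [ring_config()] (its `n_donor`/`p_donor` are ignored).
#' @param n_donor integer vector of donor counts to scan
#'   (default `0:n_positions`).
#' @return An object of class `ring_scan`: tibble `scan` (`n_donor`,
#'   `mean_pairs`, `se`), `maximizing_set`, `optimum` (midpoint).
#' @export
scan_donor_abundance <- function(config, n_donor = NULL) {
  stopifnot(inherits(config, "ring_config"))
  n <- config$n_positions
  if (is.null(n_donor)) n_donor <- 0:n
  stopifnot(all(n_donor >= 0), all(n_donor <= n))
  d <- ring_distances(n, config$diameter_nm, config$adjacent_spacing_nm)
  symmetric <- config$maturation_donor == config$maturation_acceptor &&
    config$counting_mode %in% c("pair_count", "matching")
  results <- vector("list", length(n_donor))
  names(results) <- as.character(n_donor)
  with_local_seed(config$seed, {
    for (i in seq_along(n_donor)) {
      g <- n_donor[i]
      comp <- as.character(n - g)
      if (symmetric && comp %in% names(results) && !is.null(results[[comp]])) {
        # antithetic complement: identical counts under the swap symmetry
        results[[i]] <- results[[comp]]
        next
      }
      cfg_g <- config
      cfg_g$n_donor <- as.integer(g)
      labels <- assign_labels(cfg_g)
      fluor <- apply_maturation(labels, cfg_g)
      counts <- count_fret_pairs(labels, fluor, d, cfg_g$fret_radius_nm,
                                 cfg_g$counting_mode)
      results[[i]] <- list(mean = mean(counts),
                           se = sd(counts) / sqrt(length(counts)))
    }
  })
  scan <- tibble(
    n_donor = as.integer(n_donor),
    mean_pairs = unname(vapply(results, function(r) r$mean, numeric(1))),
    se = unname(vapply(results, function(r) r$se, numeric(1)))
  )
  best <- which.max(scan$mean_pairs)
  thr <- sqrt(scan$se^2 + scan$se[best]^2)
  keep <- scan$mean_pairs >= scan$mean_pairs[best] - thr
  maximizing <- scan$n_donor[keep]
  structure(
    list(scan = scan, maximizing_set = maximizing,
         optimum = mean(range(maximizing)), config = config),
    class = "ring_scan"
  )
}

#' @export
print.ring_scan <- function(x, ...) {
  cat(sprintf("<ring_scan: optimum at n_donor = %g (set {%s}), mode %s>\n",
    x$optimum, paste(x$maximizing_set, collapse = ", "),
    x$config$counting_mode))
  invisible(x)
}

#' @method tidy ring_scan
#' @export
tidy.ring_scan <- function(x, ...) x$scan

#' @method autoplot ring_scan
#' @export
autoplot.ring_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$n_donor, y = .data$mean_pairs)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_pairs - .data$se,
                                          ymax = .data$mean_pairs + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Donors per ring", y = "Mean FRET pairs") +
    ggplot2::theme_minimal()
}

#' Correction factor for biased donor/acceptor incorporation
#'
#' When a structure preferentially recruits donor- or acceptor-labeled
#' molecules, the number of FRET pairs falls below its balanced-abundance
#' value, so the measured proximity ratio under-reports FRET. The
#' correction factor is the ratio of the mean pair count at balanced
#' abundance to the mean at the actual abundance (>= 1), applied
#' multiplicatively to the measured proximity ratio.
#'
#' @param x a `ring_scan` from [scan_donor_abundance()], or a
#'   [ring_config()] (a scan is then run internally).
#' @param n_donor the actual donor count per ring.
#' @return A scalar factor >= 1 (up to Monte Carlo noise).
#' @export
bias_correction_factor <- function(x, n_donor) {
  if (inherits(x, "ring_config")) x <- scan_donor_abundance(x)
  stopifnot(inherits(x, "ring_scan"))
  scan <- x$scan
  n <- x$config$n_positions
  balanced <- c(floor(n / 2), ceiling(n / 2))
  if (!all(balanced %in% scan$n_donor) || !(n_donor %in% scan$n_donor)) {
    abort("Scan must cover the balanced abundance and `n_donor`.",
      class = "fretcal_input_error")
  }
  ref <- mean(scan$mean_pairs[scan$n_donor %in% balanced])
  at <- scan$mean_pairs[scan$n_donor == n_donor]
  if (at <= 0) {
    abort(sprintf("Mean pair count at n_donor = %d is zero: correction infinite.",
      n_donor), class = "fretcal_domain_error")
  }
  ref / at
}
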