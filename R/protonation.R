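#' Number of protonation patterns
#'
#' Exact binomial coefficient `C(n, k)`: the number of ways to place `k`
#' protons on `n` protonatable sites. Computed by stepwise multiplicative
#' integer arithmetic (each intermediate is an exact integer), exact for
#' results below 2^53.
#'
#' @param n Number of protonatable sites (>= 0).
#' @param k Total charge, i.e. number of protons (0 <= k <= n).
#' @return The count as a numeric scalar.
#' @export
pattern_count <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (n < 0 || k < 0 || k != round(k) || n != round(n))
    stop("n and k must be non-negative integers", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) r <- r * (n - k + i) / i
  round(r)
}

#' Table of protonatable sites
#'
#' @param index 1-based contiguous site indices.
#' @param residue_type One of `"R"`, `"K"`, `"H"`, `"N-terminus"` per site.
#' @param x,y,z Coordinates in Angstrom.
#' @return Data frame of class `site_table`.
#' @export
site_table <- function(index, residue_type, x, y, z) {
  index <- as.integer(index)
  if (!identical(sort(index), seq_along(index)))
    stop("site indices must be unique and contiguous from 1", call. = FALSE)
  ok <- residue_type %in% c("R", "K", "H", "N-terminus")
  if (!all(ok))
    stop("residue_type must be one of R, K, H, N-terminus", call. = FALSE)
  st <- data.frame(index = index, residue_type = residue_type,
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  st <- st[order(st$index), , drop = FALSE]
  rownames(st) <- NULL
  class(st) <- c("site_table", "data.frame")
  st
}

#' Read/write a protonatable-site table (CSV: index,residue_type,x,y,z)
#'
#' @param path File path.
#' @return `read_site_table` returns a [site_table()].
#' @export
read_site_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  site_table(d$index, d$residue_type, d$x, d$y, d$z)
}

#' @param sites A [site_table()].
#' @rdname read_site_table
#' @export
write_site_table <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.bits_to_string <- function(occ) paste(as.integer(occ), collapse = "")
.string_to_bits <- function(bits) {
  v <- as.integer(strsplit(bits, "")[[1]])
  if (anyNA(v) || any(!v %in% 0:1)) stop("pattern must be a 0/1 string", call. = FALSE)
  v == 1L
}

#' Draw a uniformly random protonation pattern
#'
#' Places exactly `k` protons on `n` sites, uniformly over all `C(n, k)`
#' binary patterns.
#'
#' @param n Number of sites.
#' @param k Number of protons.
#' @return A 0/1 string of length `n` with exactly `k` ones.
#' @export
random_pattern <- function(n, k) {
  if (k > n || k < 0) stop("need 0 <= k <= n", call. = FALSE)
  occ <- rep(FALSE, n)
  if (k > 0) occ[sample.int(n, k)] <- TRUE
  .bits_to_string(occ)
}

#' Number of protonated arginines in a pattern
#'
#' @param bits 0/1 pattern string.
#' @param sites A [site_table()].
#' @return Count of `'1'` bits at R-type sites.
#' @export
arg_count <- function(bits, sites) {
  occ <- .string_to_bits(bits)
  if (length(occ) != nrow(sites)) stop("pattern length != number of sites", call. = FALSE)
  sum(occ & sites$residue_type == "R")
}

## Pairwise Coulomb energy matrix (kJ/mol) between all sites; diagonal 0.
.pair_energy <- function(sites, relative_permittivity = 1) {
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  e <- matrix(0, nrow(d), ncol(d))
  off <- d > 0
  e[off] <- .const$kC / (relative_permittivity * d[off])
  e
}

#' Coulomb electrostatic energy of a protonation pattern
#'
#' Sum of pairwise `kC / (eps_r * r_ij)` over all pairs of occupied sites,
#' with `kC = 1389.35 kJ A/mol` (unit elementary charges). Vacuum
#' permittivity (`eps_r = 1`) by default, appropriate for gas-phase ions.
#'
#' @param bits 0/1 pattern string.
#' @param sites A [site_table()].
#' @param relative_permittivity Relative permittivity (> 0).
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(bits, sites, relative_permittivity = 1) {
  occ <- which(.string_to_bits(bits))
  if (length(occ) < 2L) return(0)
  xyz <- as.matrix(sites[occ, c("x", "y", "z")])
  d <- stats::dist(xyz)
  if (any(d == 0))
    stop("singularity: coincident occupied sites", call. = FALSE)
  sum(.const$kC / (relative_permittivity * d))
}

.scored_frame <- function(bits, energy, sites) {
  ac <- vapply(bits, arg_count, 0L, sites = sites, USE.NAMES = FALSE)
  df <- data.frame(bits = bits, energy = energy, arg_count = ac,
                   stringsAsFactors = FALSE)
  df <- df[order(df$energy, df$bits), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Metropolis Monte-Carlo minimization of Coulomb energy
#'
#' Random walk over protonation patterns at fixed total charge `k`: each
#' move swaps one occupied with one unoccupied site and is accepted by the
#' Metropolis criterion at `temperature_param` (in kJ/mol). Every distinct
#' pattern visited is recorded with its exact Coulomb energy. With
#' `temperature_param = NULL` the temperature is calibrated from 200 probe
#' swaps so that a typical uphill move is accepted with probability ~0.5.
#' Optional geometric annealing cools the chain to 1 percent of the start
#' temperature over the run.
#'
#' @param sites A [site_table()].
#' @param k Total charge (number of protons).
#' @param steps Number of Metropolis moves (>= 1).
#' @param temperature_param Metropolis temperature in energy units (kJ/mol),
#'   or NULL for automatic calibration.
#' @param relative_permittivity Passed to the Coulomb score.
#' @param anneal Logical; geometric cooling schedule.
#' @param seed Optional RNG seed for a self-contained reproducible run.
#' @return Data frame of distinct visited patterns (`bits`, `energy`,
#'   `arg_count`), sorted ascending by energy, ties broken lexicographically
#'   by bits.
#' @export
monte_carlo_minimize <- function(sites, k, steps = 5e4, temperature_param = NULL,
                                 relative_permittivity = 1, anneal = FALSE,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sites)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  if (k == 0 || k == n) {
    bits <- paste(rep(if (k == 0) "0" else "1", n), collapse = "")
    return(.scored_frame(bits, coulomb_energy(bits, sites, relative_permittivity), sites))
  }
  P <- .pair_energy(sites, relative_permittivity)
  occ <- rep(FALSE, n); occ[sample.int(n, k)] <- TRUE
  energy_of <- function(o) { w <- which(o); sum(P[w, w]) / 2 }
  E <- energy_of(occ)
  ## temperature calibration: median |dE| of random probe swaps
  if (is.null(temperature_param)) {
    probes <- replicate(200, {
      i <- sample(which(occ), 1); j <- sample(which(!occ), 1)
      w <- which(occ); w <- w[w != i]
      sum(P[j, w]) - sum(P[i, w])
    })
    temperature_param <- max(stats::median(abs(probes)) / log(2), 1e-9)
  }
  cool <- if (anneal) 0.01^(1 / steps) else 1
  temp <- temperature_param
  seen <- new.env(parent = emptyenv())
  assign(.bits_to_string(occ), E, envir = seen)
  for (s in seq_len(steps)) {
    i <- sample(which(occ), 1L)
    j <- sample(which(!occ), 1L)
    w <- which(occ); w <- w[w != i]
    dE <- sum(P[j, w]) - sum(P[i, w])
    if (dE <= 0 || stats::runif(1) < exp(-dE / temp)) {
      occ[i] <- FALSE; occ[j] <- TRUE
      key <- .bits_to_string(occ)
      if (is.null(seen[[key]])) {
        w2 <- which(occ)
        seen[[key]] <- sum(P[w2, w2]) / 2  # exact recompute, no drift
      }
    }
    temp <- temp * cool
  }
  keys <- ls(seen)
  .scored_frame(keys, vapply(keys, function(kk) seen[[kk]], 0), sites)
}

#' Exhaustively score all protonation patterns
#'
#' Brute-force enumeration of all `C(n, k)` patterns with their Coulomb
#' energies; the independent reference for the Monte-Carlo sampler on
#' systems small enough to enumerate.
#'
#' @param sites A [site_table()].
#' @param k Total charge.
#' @param relative_permittivity Passed to the Coulomb score.
#' @param max_patterns Safety cap on `C(n, k)`.
#' @return Data frame as in [monte_carlo_minimize()].
#' @export
enumerate_patterns <- function(sites, k, relative_permittivity = 1,
                               max_patterns = 2e5) {
  n <- nrow(sites)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  npat <- pattern_count(n, k)
  if (npat > max_patterns)
    stop(sprintf("C(%d,%d) = %g exceeds max_patterns", n, k, npat), call. = FALSE)
  P <- .pair_energy(sites, relative_permittivity)
  combos <- utils::combn(n, k)
  energy <- vapply(seq_len(ncol(combos)), function(i) {
    w <- combos[, i]
    sum(P[w, w]) / 2
  }, 0)
  bits <- vapply(seq_len(ncol(combos)), function(i) {
    occ <- rep(FALSE, n); occ[combos[, i]] <- TRUE
    .bits_to_string(occ)
  }, "")
  .scored_frame(bits, energy, sites)
}

#' MMSA selection of arginine-rich low-energy patterns
#'
#' The multiple-run-multiple-states-Arg rule: take the `n_lowest`
#' lowest-energy patterns, stably re-sort them by decreasing number of
#' protonated arginines (energy order preserved within equal counts), and
#' keep the first `n_select`. Duplicate patterns beyond their first
#' occurrence are ignored.
#'
#' @param scored Data frame (`bits`, `energy`, `arg_count`) sorted
#'   ascending by energy, e.g. from [monte_carlo_minimize()].
#' @param n_lowest Size of the low-energy pool (default 100).
#' @param n_select Number of patterns to keep (default 10).
#' @return The selected rows, with a `rank` column.
#' @export
mmsa_select <- function(scored, n_lowest = 100, n_select = 10) {
  stopifnot(is.data.frame(scored),
            all(c("bits", "energy", "arg_count") %in% names(scored)))
  scored <- scored[!duplicated(scored$bits), , drop = FALSE]
  if (is.unsorted(scored$energy))
    stop("scored patterns must be sorted ascending by energy", call. = FALSE)
  if (nrow(scored) < n_select)
    stop(sprintf("insufficient pool: %d patterns < n_select = %d",
                 nrow(scored), n_select), call. = FALSE)
  pool <- utils::head(scored, n_lowest)
  pool <- pool[order(-pool$arg_count, method = "radix"), , drop = FALSE]  # stable
  out <- utils::head(pool, n_select)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
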