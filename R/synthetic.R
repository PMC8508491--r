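#' Plan for a synthetic CID spectrum series
#'
#' Describes the ground truth from which [generate_cid_series()] renders
#' spectra: the Boltzmann survival curve of the educt (percent/volts), the
#' voltage schedule, replicate count, multiplicative noise level and the
#' three co-occurring species with their charge-state envelopes. Default
#' species masses approximate the RNase S system (complex 13708.2 Da
#' splitting into an 11541.9 Da protein and a 2166.3 Da peptide, average
#' masses computed from the public ribonuclease A sequence); they are plan
#' fields, never algorithm constants.
#'
#' @param boltzmann List `a1`, `a2` (percent), `x0`, `dx` (volts) of the
#'   planted survival curve (`a1 > a2 >= 0`).
#' @param schedule Strictly increasing voltage steps (volts).
#' @param replicates Number of replicate series.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   intensity noise (0 = noiseless).
#' @param seed RNG seed: generation is a pure function of (plan, seed).
#' @param base_amplitude Total ion current scale (counts).
#' @param species List of species entries, each a list with `def`
#'   ([species_definition()]), `center_charge` (envelope apex charge state)
#'   and `sigma_mz` (envelope width in Thomson).
#' @return Object of class `series_plan`.
#' @export
series_plan <- function(boltzmann = list(a1 = 86.00, a2 = 8.77, x0 = 12.50, dx = 2.30),
                        schedule = c(4, 8, 11, 13, 15, 17, 20, 30, 50),
                        replicates = 3, noise_cv = 0.02, seed = 1,
                        base_amplitude = 1000,
                        species = default_species_plan()) {
  stopifnot(boltzmann$a1 > boltzmann$a2, boltzmann$a2 >= 0, boltzmann$dx > 0)
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly increasing", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  roles <- vapply(species, function(s) s$def$role, "")
  if (sum(roles == "educt") != 1L)
    stop("exactly one species must have role 'educt'", call. = FALSE)
  structure(list(boltzmann = boltzmann, schedule = schedule,
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 seed = as.integer(seed), base_amplitude = base_amplitude,
                 species = species),
            class = "series_plan")
}

#' Default three-species plan approximating the RNase S system
#'
#' @return List of species entries for [series_plan()].
#' @export
default_species_plan <- function() {
  list(
    list(def = species_definition("complex", 13708.2, 5:9, role = "educt"),
         center_charge = 7, sigma_mz = 250),
    list(def = species_definition("protein", 11541.9, 4:8, role = "product"),
         center_charge = 6, sigma_mz = 300),
    list(def = species_definition("peptide", 2166.3, 1:3, role = "product"),
         center_charge = 2, sigma_mz = 400)
  )
}

#' Generate a synthetic CID spectrum series with known ground truth
#'
#' At each voltage step the educt fraction `f` follows the planted
#' Boltzmann curve (as a fraction of `base_amplitude`); each product's
#' envelope amplitude is `(1 - f) * base_amplitude`, mirroring that one
#' dissociated complex yields one of each product, so the educt apex plus
#' the mean product apex is conserved across the series. Every species is
#' rendered as Gaussian-envelope peak heights at the exact theoretical m/z
#' of its charge states; multiplicative log-normal noise (unit mean,
#' coefficient of variation `noise_cv`) is applied per peak.
#'
#' @param plan A [series_plan()].
#' @return List with `spectra` (data frame `replicate`, `delta_cv`, and a
#'   `spectrum` list-column) and `truth` (the plan's Boltzmann parameters,
#'   species table and seed).
#' @export
generate_cid_series <- function(plan) {
  stopifnot(inherits(plan, "series_plan"))
  set.seed(plan$seed)
  bz <- plan$boltzmann
  sdlog <- if (plan$noise_cv > 0) sqrt(log(1 + plan$noise_cv^2)) else 0
  rows <- list(); specs <- list(); i <- 0L
  for (r in seq_len(plan$replicates)) {
    for (v in plan$schedule) {
      f <- boltzmann_curve(v, bz$a1, bz$a2, bz$x0, bz$dx) / 100
      mz <- numeric(0); int <- numeric(0)
      for (sp in plan$species) {
        amp <- plan$base_amplitude * if (sp$def$role == "educt") f else (1 - f)
        mu <- expected_mz(sp$def$mass, sp$center_charge)
        for (z in sp$def$charge_range) {
          mzz <- expected_mz(sp$def$mass, z)
          h <- amp * exp(-(mzz - mu)^2 / (2 * sp$sigma_mz^2))
          if (sdlog > 0) h <- h * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          mz <- c(mz, mzz); int <- c(int, h)
        }
      }
      i <- i + 1L
      rows[[i]] <- data.frame(replicate = r, delta_cv = v)
      specs[[i]] <- new_spectrum(mz, int, v,
                                 label = sprintf("rep%d_cv%g", r, v))
    }
  }
  idx <- do.call(rbind, rows)
  idx$spectrum <- specs
  list(spectra = idx,
       truth = list(boltzmann = bz, schedule = plan$schedule,
                    replicates = plan$replicates, noise_cv = plan$noise_cv,
                    seed = plan$seed, species = plan$species))
}

#' Write a generated CID series as peak-list files plus a manifest
#'
#' @param series Result of [generate_cid_series()].
#' @param dir Output directory (created if missing).
#' @return Path to the manifest CSV.
#' @export
write_cid_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- series$spectra
  files <- sprintf("rep%d_cv%g.txt", idx$replicate, idx$delta_cv)
  for (i in seq_len(nrow(idx)))
    write_peak_list(idx$spectrum[[i]], file.path(dir, files[i]))
  manifest <- data.frame(file = files, delta_cv = idx$delta_cv,
                         replicate = idx$replicate)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  mp
}

## Fixed-column PDB ATOM record writer; format validated against
## bio3d::read.pdb round trips in the test suite.
.pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z, element) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, x, y, z, 1, 0, element)
}

#' Write a multi-model structure ensemble as PDB text
#'
#' @param models List of data frames, one per model, each with columns
#'   `chain`, `residue_number`, `residue_name`, `atom_name`, `x`, `y`, `z`,
#'   `element`.
#' @param path Optional output file; when NULL the lines are returned.
#' @return Character vector of PDB lines (invisibly when written to file).
#' @export
write_ensemble <- function(models, path = NULL) {
  out <- character(0)
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    a <- models[[m]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, vapply(seq_len(nrow(a)), function(i)
      .pdb_atom_line(i, a$atom_name[i], a$residue_name[i], a$chain[i],
                     a$residue_number[i], a$x[i], a$y[i], a$z[i],
                     a$element[i]), ""))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Generate a structure ensemble with planted inter-chain contacts
#'
#' Builds a two-chain multi-model PDB (peptide chain `"S"`, protein chain
#' `"P"`) in which each planned contact pair sits at 3.5 Angstrom in
#' exactly its planned number of models and at more than 6 Angstrom
#' otherwise; distinct pairs occupy spatial slots at least 30 Angstrom
#' apart, so no unplanned contacts can arise. The fixture is synthetic
#' geometry: residues are laid out for contact bookkeeping, not for
#' stereochemical realism.
#'
#' @param n_models Number of models in the ensemble.
#' @param contact_plan Named list: names are peptide residue numbers, each
#'   value an integer vector of recurrence multiplicities (one per planted
#'   contact pair, each between 1 and `n_models`); an empty vector plants a
#'   contact-free residue (ratio 0).
#' @param seed RNG seed (which models realize a pair is sampled).
#' @return List with `pdb` (PDB text lines), `truth` (data frame
#'   `peptide_residue`, `position_contacts`, `sum_contacts`, `ratio`) and
#'   the chain identifiers used.
#' @export
generate_contact_ensemble <- function(n_models, contact_plan, seed = 1) {
  set.seed(seed)
  atom_pool <- c("CB", "CG", "CD", "CE", "CZ", "SD", "OG", "OD1", "ND1", "NZ")
  res_ids <- as.integer(names(contact_plan))
  if (anyNA(res_ids)) stop("contact_plan names must be residue numbers", call. = FALSE)
  for (mult in contact_plan) {
    if (length(mult) > length(atom_pool))
      stop("plan error: too many pairs for one residue", call. = FALSE)
    if (any(mult < 1) || any(mult > n_models))
      stop("plan error: multiplicities must be in 1..n_models", call. = FALSE)
  }
  ## lay out one spatial slot per planted pair along x
  pairs <- list(); s <- 0L
  for (ri in seq_along(res_ids)) {
    mult <- contact_plan[[ri]]
    for (j in seq_along(mult)) {
      s <- s + 1L
      pairs[[s]] <- list(res = res_ids[ri], atom = atom_pool[j],
                         prot_res = 200L + s, base_x = 30 * s,
                         models = sort(sample.int(n_models, mult[j])))
    }
  }
  models <- lapply(seq_len(n_models), function(m) {
    rows <- list(); k <- 0L
    if (length(pairs) == 0L) {
      ## lone distant protein anchor so both chains always exist
      k <- k + 1L
      rows[[k]] <- data.frame(chain = "P", residue_number = 199L,
                              residue_name = "GLY", atom_name = "CA",
                              x = -200, y = 0, z = 0, element = "C",
                              stringsAsFactors = FALSE)
    }
    for (p in pairs) {
      zpep <- if (m %in% p$models) 3.5 else 12.0
      k <- k + 1L
      rows[[k]] <- data.frame(chain = c("P", "S"),
                              residue_number = c(p$prot_res, p$res),
                              residue_name = c("GLY", "ALA"),
                              atom_name = c("CA", p$atom),
                              x = c(p$base_x, p$base_x), y = c(0, 0),
                              z = c(0, zpep), element = c("C", "C"),
                              stringsAsFactors = FALSE)
    }
    ## contact-free residues sit far from every slot
    for (ri in seq_along(res_ids)) {
      if (length(contact_plan[[ri]]) == 0L) {
        k <- k + 1L
        rows[[k]] <- data.frame(chain = "S", residue_number = res_ids[ri],
                                residue_name = "ALA", atom_name = "CA",
                                x = -100, y = 50 + 10 * ri, z = 0,
                                element = "C", stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  truth <- do.call(rbind, lapply(seq_along(res_ids), function(ri) {
    mult <- contact_plan[[ri]]
    pos <- length(mult); sm <- sum(mult)
    data.frame(peptide_residue = res_ids[ri], position_contacts = pos,
               sum_contacts = sm, ratio = if (pos > 0) sm / pos else 0)
  }))
  truth <- truth[order(truth$peptide_residue), , drop = FALSE]
  rownames(truth) <- NULL
  list(pdb = write_ensemble(models), truth = truth,
       peptide_chain = "S", protein_chain = "P")
}

#' Generate a random protonatable-site geometry
#'
#' Rejection-samples `n_sites` coordinates uniformly in a cubic box so that
#' all pairwise separations are at least `min_separation`; site residue
#' types follow `residue_mix`. Deterministic under `seed`.
#'
#' @param n_sites Number of sites.
#' @param residue_mix Named integer vector over types `R`, `K`, `H`,
#'   `N-terminus`; counts must sum to `n_sites`.
#' @param box Cube edge length (Angstrom).
#' @param min_separation Minimum pairwise distance (Angstrom).
#' @param seed RNG seed.
#' @param max_attempts Total rejection budget before declaring the packing
#'   infeasible.
#' @return A [site_table()].
#' @export
generate_site_geometry <- function(n_sites = 20,
                                   residue_mix = c(R = 4, K = 10, H = 4, "N-terminus" = 2),
                                   box = 40, min_separation = 5, seed = 1,
                                   max_attempts = 20000) {
  if (sum(residue_mix) != n_sites)
    stop("residue_mix counts must sum to n_sites", call. = FALSE)
  set.seed(seed)
  coords <- matrix(NA_real_, n_sites, 3)
  placed <- 0L; attempts <- 0L
  while (placed < n_sites) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("geometry error: packing infeasible within attempt budget", call. = FALSE)
    p <- stats::runif(3, 0, box)
    if (placed == 0L ||
        min(sqrt(colSums((t(coords[seq_len(placed), , drop = FALSE]) - p)^2))) >= min_separation) {
      placed <- placed + 1L
      coords[placed, ] <- p
    }
  }
  types <- rep(names(residue_mix), residue_mix)
  site_table(seq_len(n_sites), types, coords[, 1], coords[, 2], coords[, 3])
}
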