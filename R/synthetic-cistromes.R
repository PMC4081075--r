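#' Simulation design for multi-factor cistromes
#'
#' Describes the latent regulatory elements behind a set of simulated
#' cistromes: each factor owns `n_elements_per_factor` latent elements (its
#' peak is always present there) and every other factor drops a peak on them
#' with the pairwise probability in `shared_fraction`. Peak centres scatter
#' around the element centre with Gaussian jitter, emulating summit
#' uncertainty between ChIP-seq libraries.
#'
#' @param factors character vector of factor names (>= 1).
#' @param n_elements_per_factor latent elements owned by each factor.
#' @param shared_fraction symmetric matrix (factors x factors) of pairwise
#'   element-sharing probabilities in `[0, 1]`, unit diagonal. A scalar is
#'   expanded to a constant off-diagonal.
#' @param centre_jitter_sd sd (bp) of the Gaussian centre jitter, >= 0.
#' @param peak_halfwidth half-width (bp) of the emitted peak intervals.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param min_spacing minimum distance between latent element centres;
#'   default 4x the canonical 250 bp clustering radius so truth clusters are
#'   unambiguous, configurable to stress-test clustering.
#' @param seed RNG seed.
#' @return a `cistrome_sim_spec`.
#' @export
cistrome_sim_spec <- function(factors, n_elements_per_factor = 1000,
                              shared_fraction = 0.5, centre_jitter_sd = 20,
                              peak_halfwidth = 150,
                              chrom_lengths = c(chrSim1 = 5e7, chrSim2 = 5e7),
                              min_spacing = 1000, seed = 1) {
  nf <- length(factors)
  if (!nf) stopf("at least one factor required")
  if (is.null(dim(shared_fraction))) {
    shared_fraction <- matrix(shared_fraction[1], nf, nf)
    diag(shared_fraction) <- 1
  }
  dimnames(shared_fraction) <- list(factors, factors)
  if (!isSymmetric(unname(shared_fraction)) || any(diag(shared_fraction) != 1))
    stopf("sharing matrix must be symmetric with unit diagonal")
  if (any(shared_fraction < 0 | shared_fraction > 1))
    stopf("sharing probabilities must lie in [0, 1]")
  if (centre_jitter_sd < 0) stopf("centre_jitter_sd must be >= 0")
  if (any(chrom_lengths <= 2 * peak_halfwidth))
    stopf("chromosomes too short for the peak width")
  structure(list(factors = factors,
                 n_elements_per_factor = n_elements_per_factor,
                 shared_fraction = shared_fraction,
                 centre_jitter_sd = centre_jitter_sd,
                 peak_halfwidth = peak_halfwidth,
                 chrom_lengths = chrom_lengths,
                 min_spacing = min_spacing, seed = seed),
            class = "cistrome_sim_spec")
}

# place n points across chromosomes with a minimum pairwise spacing;
# deterministic given the RNG state
place_spaced_centres <- function(n, chrom_lengths, min_spacing, margin = 0) {
  usable <- pmax(chrom_lengths - 2 * margin, 0)
  capacity <- floor(usable / min_spacing)
  if (n > sum(capacity))
    stopf("genome too small: %d positions requested, capacity %d at spacing %d",
          n, sum(capacity), min_spacing)
  per <- floor(n * capacity / sum(capacity))
  rem <- n - sum(per)
  if (rem > 0) {
    extra <- order(capacity - per, decreasing = TRUE)[seq_len(rem)]
    per[extra] <- per[extra] + 1L
  }
  out <- lapply(seq_along(chrom_lengths), function(i) {
    k <- per[i]
    if (!k) return(NULL)
    # subtract the guaranteed spacing, place uniformly, add it back
    slack <- usable[i] - k * min_spacing
    u <- sort(runif(k, 0, slack))
    data.frame(chrom = names(chrom_lengths)[i],
               centre = as.integer(margin + floor(u) +
                                     min_spacing * seq_len(k)))
  })
  do.call(rbind, out)
}

#' Simulate multi-factor cistromes with planted co-occupancy
#'
#' Generates one cistrome per factor from latent shared elements (see
#' [cistrome_sim_spec()]) and returns, alongside the cistromes, the truth
#' table of element-to-factor membership for oracle tests.
#'
#' @param spec a [cistrome_sim_spec()].
#' @return list with `cistromes` (named list of [cistrome()]s) and `truth`
#'   (data frame: `element_id`, `owner`, `chrom`, `centre`, one logical
#'   column per factor, and `signature`).
#' @export
gen_cistromes <- function(spec) {
  stopifnot(inherits(spec, "cistrome_sim_spec"))
  with_seed(spec$seed, {
    nf <- length(spec$factors)
    n_el <- nf * spec$n_elements_per_factor
    margin <- spec$peak_halfwidth + 6 * spec$centre_jitter_sd + 1
    centres <- place_spaced_centres(n_el, spec$chrom_lengths,
                                    spec$min_spacing, margin = margin)
    owner <- rep(spec$factors, each = spec$n_elements_per_factor)
    # interleave owners along the genome so co-occupancy is position-free
    owner <- sample(owner)
    truth <- data.frame(element_id = sprintf("el_%05d", seq_len(n_el)),
                        owner = owner, chrom = centres$chrom,
                        centre = centres$centre, stringsAsFactors = FALSE)
    member <- matrix(FALSE, n_el, nf, dimnames = list(NULL, spec$factors))
    for (f in spec$factors) {
      prob <- spec$shared_fraction[cbind(owner, f)]
      prob[owner == f] <- 1
      member[, f] <- runif(n_el) < prob
    }
    cistromes <- lapply(spec$factors, function(f) {
      sel <- which(member[, f])
      jitter <- round(rnorm(length(sel), 0, spec$centre_jitter_sd))
      centre <- truth$centre[sel] + as.integer(jitter)
      cistrome(data.frame(chrom = truth$chrom[sel],
                          start = centre - spec$peak_halfwidth,
                          end = centre + spec$peak_halfwidth,
                          centre = centre,
                          score = round(rlnorm(length(sel), log(10), 0.5), 3),
                          name = paste0(f, "_", truth$element_id[sel])),
               factor = f, condition = "simulated")
    })
    names(cistromes) <- spec$factors
    for (f in spec$factors) truth[[f]] <- member[, f]
    truth$signature <- apply(member, 1, function(r)
      paste(spec$factors[r], collapse = "_"))
    list(cistromes = cistromes, truth = truth)
  })
}

#' Simulate per-element read counts for a knockdown comparison
#'
#' Element strengths are log-normal; control counts are Poisson with mean
#' proportional to strength, scaled so expected totals match `library_size`.
#' Knockdown means are multiplied by the retained-signal fraction of the
#' element's occupancy signature, emulating signature-specific loss of
#' binding on cofactor depletion.
#'
#' @param truth truth table from [gen_cistromes()] (needs `element_id` and
#'   `signature`).
#' @param depletion_map named numeric vector, signature -> retained fraction
#'   in `(0, 1]`; signatures not listed retain 1.
#' @param library_size expected total control counts (also used as the
#'   normalisation constant for both libraries).
#' @param seed RNG seed.
#' @return an [element_count_table()] with equal nominal library sizes.
#' @export
gen_element_counts <- function(truth, depletion_map, library_size = 2e6,
                               seed = 1) {
  if (!nrow(truth)) stopf("empty truth table")
  if (any(depletion_map <= 0 | depletion_map > 1))
    stopf("retained fractions must lie in (0, 1]")
  with_seed(seed, {
    strength <- rlnorm(nrow(truth), log(100), 0.4)
    mu_ctl <- strength * library_size / sum(strength)
    retained <- depletion_map[truth$signature]
    retained[is.na(retained)] <- 1
    element_count_table(
      data.frame(element_id = truth$element_id, signature = truth$signature,
                 control = rpois(nrow(truth), mu_ctl),
                 kd = rpois(nrow(truth), mu_ctl * retained),
                 stringsAsFactors = FALSE),
      lib_control = library_size, lib_kd = library_size)
  })
}
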