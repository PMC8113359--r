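#' Wright-Fisher simulation oracle for the PRF model
#'
#' A discrete forward-time Wright-Fisher simulation of a gene with
#' infinitely many independently evolving sites, used to validate the
#' quadrature-based expectations of [expected_poly_sites()].  Three site
#' classes are tracked: beneficial nonsynonymous (homozygous effect `+s`),
#' deleterious nonsynonymous (`-s`) and neutral synonymous mutations, with
#' additive fitness (heterozygotes intermediate).  Because every site is an
#' independent binomial lineage there is no selective interference, matching
#' the Poisson-field assumption by construction.
#'
#' The homozygous fitness effect is chosen so the diffusion-scale selection
#' parameter of the simulation equals the model's: the sojourn density of a
#' semidominant mutation with homozygous effect `s` in a diploid population
#' of size `N` carries the exponent `2*N*s`, which is matched to the `4*ne_s`
#' exponent of the segregating-site integrals, i.e. `s = 2*ne_s/pop_size`.
#'
#' At each sampling epoch the number of sites segregating in a sample of `m`
#' copies (drawn binomially from the population frequency, as the model
#' assumes) is accumulated as its exact conditional expectation
#' `sum_sites (1 - p^m - (1-p)^m)`, which removes sampling noise without
#' biasing the comparison; the remaining Monte-Carlo error comes from the
#' population process itself and is quantified by batch means over epochs.
#'
#' @param ne_s Scaled selection magnitude on the model scale (`>= 0`).
#' @param alpha_m Fraction of new nonsynonymous mutations that are beneficial.
#' @param mu_n_total,mu_s_total Total nonsynonymous and synonymous mutation
#'   rates per haploid genome per generation.
#' @param pop_size Diploid population size, at most 200 (the diffusion
#'   matching assumes `s` small; larger populations are unnecessary).
#' @param m Sample size in gene copies.
#' @param generations Number of generations simulated after burn-in.
#' @param burn_in Generations discarded before sampling starts.
#' @param sample_every Generations between sampling epochs.
#' @param seed Integer RNG seed.
#' @return A list with mean per-epoch segregating-site counts `seg_N`,
#'   `seg_S`, their ratio `ratio_NS` with batch-means standard error
#'   `ratio_se`, cumulative fixation counts `fix_B`, `fix_D`, `fix_S`,
#'   the per-epoch count matrix `epochs`, and the effective selection
#'   coefficient `s` used.
#' @export
wf_oracle <- function(ne_s, alpha_m, mu_n_total, mu_s_total, pop_size = 100,
                      m = 20, generations = 40000, burn_in = 4000,
                      sample_every = 200, seed = 1) {
  stopifnot(ne_s >= 0, alpha_m >= 0, alpha_m <= 1,
            mu_n_total > 0, mu_s_total > 0, m >= 2)
  if (pop_size > 200)
    stop("wf_oracle: pop_size must be <= 200 (diffusion matching assumes small s)")
  s <- 2 * ne_s / pop_size
  if (s > 0.25)
    stop("wf_oracle: implied selection coefficient ", signif(s, 3),
         " too large for the diffusion regime; reduce ne_s or raise pop_size")
  twoN <- 2L * as.integer(pop_size)
  set.seed(seed)

  ## allele counts per segregating site, one vector per class
  cnt <- list(B = integer(0), D = integer(0), S = integer(0))
  sel <- c(B = s, D = -s, S = 0)
  mu_new <- c(B = alpha_m * mu_n_total, D = (1 - alpha_m) * mu_n_total,
              S = mu_s_total)
  fix <- c(B = 0L, D = 0L, S = 0L)

  step_class <- function(counts, s_eff) {
    if (length(counts) == 0L) return(counts)
    p <- counts / twoN
    if (s_eff != 0) {
      ## additive selection: genotype fitnesses 1+s, 1+s/2, 1
      p <- p * (1 + s_eff * (1 + p) / 2) / (1 + s_eff * p)
    }
    stats::rbinom(length(counts), twoN, p)
  }

  n_epochs <- generations %/% sample_every
  epochs <- matrix(0, nrow = n_epochs, ncol = 2,
                   dimnames = list(NULL, c("seg_N", "seg_S")))
  epoch <- 0L
  total_gen <- burn_in + generations
  for (gen in seq_len(total_gen)) {
    for (cl in c("B", "D", "S")) {
      x <- step_class(cnt[[cl]], sel[[cl]])
      fixed <- sum(x == twoN)
      if (gen > burn_in) fix[[cl]] <- fix[[cl]] + fixed
      x <- x[x > 0L & x < twoN]
      n_new <- stats::rpois(1L, twoN * mu_new[[cl]])
      if (n_new > 0L) x <- c(x, rep(1L, n_new))
      cnt[[cl]] <- x
    }
    if (gen > burn_in && (gen - burn_in) %% sample_every == 0L) {
      epoch <- epoch + 1L
      seg_expect <- function(counts) {
        if (length(counts) == 0L) return(0)
        p <- counts / twoN
        sum(1 - p^m - (1 - p)^m)
      }
      epochs[epoch, "seg_N"] <- seg_expect(cnt$B) + seg_expect(cnt$D)
      epochs[epoch, "seg_S"] <- seg_expect(cnt$S)
    }
  }

  seg_N <- mean(epochs[, "seg_N"])
  seg_S <- mean(epochs[, "seg_S"])
  ## batch means to absorb autocorrelation between epochs
  n_batch <- max(10L, min(20L, n_epochs %/% 5L))
  bid <- cut(seq_len(n_epochs), n_batch, labels = FALSE)
  bratio <- tapply(epochs[, "seg_N"], bid, mean) / tapply(epochs[, "seg_S"], bid, mean)
  list(seg_N = seg_N, seg_S = seg_S,
       ratio_NS = seg_N / seg_S,
       ratio_se = stats::sd(bratio) / sqrt(n_batch),
       fix_B = fix[["B"]], fix_D = fix[["D"]], fix_S = fix[["S"]],
       epochs = epochs, s = s, m = m, pop_size = pop_size)
}
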