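#' Parameters of a synthetic RIP-qPCR experiment
#'
#' Inverse model of the percent-input calculus: each sample's Cp is
#' `base_cp - log2(effective template) + Normal(0, cp_noise_sd)`, where the
#' effective template is the gene's relative abundance times the capture
#' efficiency (IP, mock) or the input dilution (input). The default input
#' dilution `2^-6.644` is exactly the dilution encoded by the percent-input
#' correction constant (10% of extract saved as input, diluted 1:10), so on
#' noise-free tables [percent_input()] recovers `100 * efficiency`
#' algebraically. -RT rows sit at least 12 cycles above the noise-free +RT
#' Cp, comfortably past the 10-cycle contamination QC gap.
#'
#' @param abundances named numeric vector of true relative mRNA abundances.
#' @param efficiency_ip named (or scalar) capture efficiency of the specific
#'   IP per gene, fraction of input captured in `(0, 1]`; RIP experiments of
#'   this kind typically capture a few to a few tens of percent.
#' @param efficiency_mock capture efficiency of the mock IP.
#' @param input_dilution fraction of template carried by the diluted input.
#' @param cp_noise_sd Gaussian Cp measurement noise SD (cycles).
#' @param bio_reps,tech_reps biological and technical replicates.
#' @param base_cp Cp of one unit of undiluted template.
#' @param include_minus_rt simulate -RT control rows.
#' @param seed RNG seed.
#' @return Validated list of class `cp_sim_params`.
#' @export
cp_sim_params <- function(abundances = c(Taf8 = 1, Taf10 = 4),
                          efficiency_ip = 0.15, efficiency_mock = 0.002,
                          input_dilution = 2^-6.644,
                          cp_noise_sd = 0.2, bio_reps = 3L, tech_reps = 2L,
                          base_cp = 17, include_minus_rt = TRUE, seed = 1L) {
  stopifnot(length(abundances) >= 1, !is.null(names(abundances)),
            all(abundances > 0),
            all(efficiency_ip > 0), all(efficiency_ip <= 1),
            all(efficiency_mock > 0), all(efficiency_mock <= 1),
            input_dilution > 0, input_dilution <= 1,
            cp_noise_sd >= 0, bio_reps >= 1, tech_reps >= 1)
  expand_gene <- function(x) {
    if (length(x) == 1 && is.null(names(x)))
      stats::setNames(rep(x, length(abundances)), names(abundances))
    else {
      stopifnot(all(names(abundances) %in% names(x)))
      x[names(abundances)]
    }
  }
  p <- list(abundances = abundances,
            efficiency_ip = expand_gene(efficiency_ip),
            efficiency_mock = expand_gene(efficiency_mock),
            input_dilution = input_dilution, cp_noise_sd = cp_noise_sd,
            bio_reps = as.integer(bio_reps), tech_reps = as.integer(tech_reps),
            base_cp = base_cp, include_minus_rt = include_minus_rt,
            seed = seed)
  structure(p, class = "cp_sim_params")
}

#' Simulate a RIP-qPCR Cp table with known ground truth
#'
#' Generates `bio_reps * tech_reps` +RT rows (and matching -RT controls) per
#' gene and role following the log2-linear template model of
#' [cp_sim_params()]. Deterministic given the seed.
#'
#' @param params a [cp_sim_params()] object.
#' @return A [as_cp_table()] data frame; attribute `truth` carries the
#'   parameters for round-trip checks.
#' @export
simulate_cp_table <- function(params) {
  stopifnot(inherits(params, "cp_sim_params"))
  with_seed(params$seed, {
    genes <- names(params$abundances)
    rows <- list()
    for (g in genes) {
      ab <- params$abundances[[g]]
      template <- c(input = ab * params$input_dilution,
                    ip = ab * params$efficiency_ip[[g]],
                    mock = ab * params$efficiency_mock[[g]])
      for (role in names(template)) {
        clean <- params$base_cp - log2(template[[role]])
        for (b in seq_len(params$bio_reps)) for (t in seq_len(params$tech_reps)) {
          cp <- clean + if (params$cp_noise_sd > 0)
            stats::rnorm(1, 0, params$cp_noise_sd) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, role = role, rt = "plus", bio_rep = b, tech_rep = t,
            cp = cp)
          if (params$include_minus_rt) {
            cpm <- clean + 12 + abs(stats::rnorm(1, 0, 1))
            rows[[length(rows) + 1L]] <- data.frame(
              gene = g, role = role, rt = "minus", bio_rep = b, tech_rep = t,
              cp = if (cpm > 45) NA_real_ else cpm)
          }
        }
      }
    }
    out <- as_cp_table(do.call(rbind, rows))
    attr(out, "truth") <- params
    out
  })
}
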