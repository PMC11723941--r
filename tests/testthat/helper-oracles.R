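# Shared fixtures and independent oracles for the test suite.

# Random point on the frequency simplex.
random_state <- function() {
  f <- runif(4)
  as_state_vec(f / sum(f))
}

as_state_vec <- function(f) population_state(f[1], f[2], f[3], f[4])

random_params <- function(model = 1) {
  cms_params(g = runif(1, 0.5, 2.5), alpha = runif(1, 1, 8),
             s = runif(1, 0, 0.8), d = runif(1, 0, 0.9),
             e_m = runif(1, 0, 0.95), model = model)
}

# Seed-by-seed enumeration oracle for one generation: loop explicitly over
# every (mother genotype x pollen donor genotype x donor gamete) combination
# plus the selfing classes, tally offspring genotypes, and normalize. Coded
# independently of the package's pollen-haplotype shortcut (P_X, P_Y).
enumeration_step <- function(state, params) {
  f <- setNames(as.numeric(state), c("XXn", "XYn", "XXc", "XYc"))
  with(params, {
    pollen <- c(XXn = f[["XXn"]] * P_h,
                XYn = f[["XYn"]] * alpha * P_h,
                XXc = 0,
                XYc = f[["XYc"]] * (1 - e_m) * alpha * P_h)
    total_pollen <- sum(pollen)
    # gametes from each donor: proportion of X vs Y pollen
    donor_gametes <- list(XXn = c(X = 1, Y = 0), XYn = c(X = 0.5, Y = 0.5),
                          XXc = c(X = 1, Y = 0), XYc = c(X = 0.5, Y = 0.5))
    outx <- if (total_pollen <= 0) 0
            else if (model == 1) 1
            else min(1, total_pollen / P_h)

    counts <- c(XXn = 0, XYn = 0, XXc = 0, XYc = 0)
    viable <- 0
    # mothers: XXn hermaphrodites and XXc females
    for (mother in c("XXn", "XXc")) {
      ovules <- if (mother == "XXn") G_h * f[["XXn"]] else g * G_h * f[["XXc"]]
      cyto <- if (mother == "XXn") "n" else "c"
      prior <- if (mother == "XXn") s * ovules else 0
      outcrossed <- (ovules - prior) * outx
      delayed <- if (mother == "XXn" && model == 3) (ovules - prior) * (1 - outx) else 0
      # selfed seed: mother XX selfing with own X pollen -> all XX, own cytotype
      selfed_viable <- (prior + delayed) * (1 - d)
      counts[paste0("XX", cyto)] <- counts[paste0("XX", cyto)] + selfed_viable
      viable <- viable + selfed_viable
      # outcrossed seed, donor by donor, gamete by gamete
      if (outcrossed > 0 && total_pollen > 0) {
        for (donor in names(pollen)) {
          share <- pollen[[donor]] / total_pollen
          for (gam in c("X", "Y")) {
            n_seed <- outcrossed * share * donor_gametes[[donor]][[gam]]
            kid <- paste0(if (gam == "X") "XX" else "XY", cyto)
            counts[kid] <- counts[kid] + n_seed
            viable <- viable + n_seed
          }
        }
      }
    }
    if (viable <= 0) return(NULL)  # extinction
    as_state_vec(counts / viable)
  })
}

# baseline parameter set sitting inside the trioecy band of model 1
trioecy_params <- function(g = 1.1)
  cms_params(g = g, alpha = 5, s = 0.4, d = 0.1, e_m = 0.8, model = 1)
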