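# Shared fixtures, built in code.

# two-compound toy series on a 3-atom shared core
toy_sketches <- function() {
  core <- data.frame(element = c("C", "C", "O"), x = c(0, 1.5, 3.0),
                     y = c(0, 0, 0.5))
  bonds <- data.frame(a1 = c(1, 2), a2 = c(2, 3), order = c(1, 2))
  s1 <- sketch("cmp1", rbind(core, data.frame(element = "Cl", x = 0, y = 1.9)),
               rbind(bonds, data.frame(a1 = 1, a2 = 4, order = 1)))
  s2 <- sketch("cmp2", rbind(core, data.frame(element = "F", x = 0, y = 1.9)),
               rbind(bonds, data.frame(a1 = 1, a2 = 4, order = 1)))
  list(s1, s2)
}

# small canvas keeps brute-force pixel oracles cheap
small_canvas <- function() canvas_spec(width = 60, height = 50, scale = 5,
                                       origin = c(30, 25))

# published decomposition rows for the six representative docking ligands
table4_rows <- function() {
  data.frame(id = c("B9", "A7", "B1", "P1", "Mesotrione_Cryst", "Mesotrione_69"),
             reported_total = c(-7.99, -9.12, -8.56, -9.57, -6.36, -6.56),
             electrostatic = c(-2.24, -1.68, -2.32, -1.48, -2.81, -2.05),
             vdw = c(-7.55, -8.33, -7.73, -9.58, -3.97, -6.01),
             internal = c(-0.41, -0.63, -0.05, -1.39, -1.06, -2.15),
             torsional = c(1.79, 0.89, 1.49, 1.49, 1.49, 1.49),
             stringsAsFactors = FALSE)
}

# Constructed Williams outlier scenario: one sample shifted by 5 sigma, the
# clean background built so that no clean studentized residual exceeds
# 2 sigma (the stated construction). Deterministic: scans a fixed seed
# sequence and returns the first realisation meeting the premise.
williams_outlier_fixture <- function(base_seed = 1L, index = 13L,
                                     max_tries = 12L) {
  for (k in seq_len(max_tries)) {
    cfg <- generator_config(seed = base_seed + 1000L * (k - 1L),
                            noise_cap_sd = 2,
                            outlier = list(index = index, shift_sd = 5))
    ds <- generate_dataset(cfg)
    desc <- build_descriptor_matrix(ds$sketches, "r_vdw")
    A <- select_components(desc, ds$activities$pki, 10)$A
    model <- fit_pls(desc, ds$activities$pki, A)
    w <- williams(model, desc, ds$activities$pki, ids = ds$activities$id)
    clean <- abs(w$stud_residual[-index])
    if (max(clean) <= 2) return(list(williams = w, index = index, A = A))
  }
  stop("could not realise the constructed outlier scenario")
}

# per-channel battery statistics as printed in the published validation
# table (inputs for the cross-channel summariser)
published_channel_stats <- function() {
  m <- rbind(r2 = c(0.9022, 0.8932, 0.9057),
             q2 = c(0.5819, 0.5868, 0.5939),
             r2_pred = c(0.7315, 0.7676, 0.7098))
  colnames(m) <- c("r_vdw", "epsilon", "ratio")
  m
}
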