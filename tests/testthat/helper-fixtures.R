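# Small builders shared across test files.

three_materials <- function() {
  list(
    material_record("SWCNT", 40, bet_ssa = 1040, esa = 138.2,
                    geometry = bundle_geometry(3, 65), iron_pct = 0.23,
                    ssa_dose_printed = 4.16e-2, esa_dose_printed = 5.52e-3),
    material_record("CNF", 120, bet_ssa = 45, esa = 21,
                    geometry = cnf_geometry(109, 53), iron_pct = 1.4,
                    ssa_dose_printed = 5.4e-3, esa_dose_printed = 2.52e-3),
    material_record("asbestos", 120, bet_ssa = 8.3, esa = 8.3,
                    iron_pct = 18,
                    ssa_dose_printed = 9.6e-4, esa_dose_printed = 9.6e-4))
}

# n synthetic materials with non-collinear BET and effective surface doses
synthetic_dose_table <- function(n = 8) {
  esa_per_g <- seq(20, 300, length.out = n)
  bet_per_g <- rev(seq(50, 1100, length.out = n)) # deliberately not
                                                  # proportional to esa
  build_dose_table(lapply(seq_len(n), function(i)
    material_record(sprintf("M%02d", i), mass_dose_ug = 40 + 10 * i,
                    bet_ssa = bet_per_g[i], esa = esa_per_g[i])))
}

# direct covariance / sd oracle, independent of stats::cor
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
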