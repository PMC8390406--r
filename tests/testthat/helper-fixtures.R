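# shared fixtures built in code

make_readings <- function(times, absorbance, sample_id = "s1",
                          fraction = "mixed", enzyme_class = "protease",
                          replicate = 1L) {
  tibble::tibble(
    sample_id = sample_id, fraction = fraction,
    enzyme_class = enzyme_class, replicate = replicate,
    time_h = times, absorbance = absorbance
  )
}

# frozen noisy near-flat trace (6 points around 0.30 AU); generated once with
# rnorm(6, 0, 0.01) and frozen so the independent R2 oracle is reproducible
flat_noisy_trace <- function() {
  list(
    times = c(0, 0.25, 0.5, 0.75, 1.0, 1.25),
    absorbance = 0.30 + c(-0.00626, 0.00184, -0.00836, 0.01595, 0.00330, -0.00820)
  )
}

# integer-valued trace engineered so OLS gives R^2 = 0.7 exactly:
# y = t + p with p = (1, -2, 1, 0) orthogonal to the centered times,
# SSE = 6, SST = 20
boundary_r2_trace <- function() {
  list(times = c(0, 1, 2, 5), absorbance = c(1, -1, 3, 5))
}

# independent spreadsheet-style OLS oracle (squared Pearson correlation and
# textbook normal-equation slope), a different route than the package's
# sum-of-squares decomposition
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  list(slope = slope, r2 = stats::cor(x, y)^2)
}

# closed form for a uniform bed: k * M * T * (n + 1) / (2n) / V_f, in mg COD/L
closed_form_capacity <- function(k_g_cod_kg_vs_h, m_kg_vs, t_h, n, feed_m3) {
  k_g_cod_kg_vs_h * m_kg_vs * t_h * (n + 1) / (2 * n) / feed_m3
}

uniform_activities <- function(a, enzyme = "alpha_glucosidase") {
  activities_bed_wide(stats::setNames(a, enzyme))
}

# small uniform-activity state for closed-form checks
uniform_state <- function(vs_kg = 1000, feed_m3 = 1000) {
  reactor_state(
    reactor_volume_m3 = 1000, ts_g_l = vs_kg / 1000, vs_ts_ratio = 1,
    svi30_ml_g = 40, bed_porosity = 0.52, feed_batch_m3 = feed_m3,
    feeding_duration_h = 1
  )
}
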