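method_path <- function() {
  system.file("extdata", "method_fish.yaml", package = "halovalid")
}

load_method <- function() read_method_definition(method_path())

components_path <- function() {
  system.file("extdata", "uncertainty_components.csv", package = "halovalid")
}

# independent two-pass sample SD oracle (n-1 denominator)
sd_oracle <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# closed-form simple-linear-regression oracle
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# rescale a vector to an exact sample mean and SD
with_mean_sd <- function(x, mean, sd) {
  mean + (x - base::mean(x)) / stats::sd(x) * sd
}

# 95% sampling band for a sample SD (or RSD) around its true value
sd_band <- function(true, n, conf = 0.95) {
  a <- (1 - conf) / 2
  true * sqrt(stats::qchisq(c(a, 1 - a), df = n - 1) / (n - 1))
}

# small three-compound panel for focused simulator tests
tiny_panel <- function() {
  analyte_panel(data.frame(
    name = c("A1", "A2", "IS"),
    role = c("analyte", "analyte", "internal_standard"),
    is_ref = c("IS", "IS", ""),
    purity_pct = c(98, 96, 99),
    is_conc = c(NA, NA, 10),
    stringsAsFactors = FALSE))
}

tiny_params <- function(me = c(0, 0, 0), recovery = c(100, 100, 100),
                        rrf = c(2, 0.5, 1)) {
  data.frame(name = c("A1", "A2", "IS"), rrf_true = rrf, me_true_pct = me,
             recovery_true_pct = recovery, stringsAsFactors = FALSE)
}
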