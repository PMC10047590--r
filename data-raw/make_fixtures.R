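# Builds the bundled synthetic chromophore tables under inst/extdata/.
#
# The hemoglobin table is a parametric stand-in for a measured molar
# extinction compilation: sums of Gaussian bands plus a Soret-edge tail and a
# long-wavelength shoulder, with the visible band positions and magnitudes set
# to the well-established literature values (oxyhemoglobin beta band 542 nm,
# alpha band 577 nm, each ~5.3-5.6e4 /cm/M; deoxyhemoglobin single visible
# band near 556 nm, ~5.3e4 /cm/M). It is labelled synthetic: suitable for
# simulation, testing and worked examples, not for quantitative work on
# measured clinical spectra.

lambda <- seq(450, 650, by = 1)

gauss <- function(l, mu, sigma, amp) amp * exp(-((l - mu)^2) / (2 * sigma^2))

# Oxyhemoglobin: Soret edge + beta (542) + alpha (577) bands + small floor
eps_hbo2 <- gauss(lambda, 420, 25, 130000) +
  gauss(lambda, 542, 11, 53200) +
  gauss(lambda, 577, 9.5, 55500) +
  1500 * exp(-(lambda - 450) / 120) + 300

# Deoxyhemoglobin: Soret edge + single visible band (556) + red shoulder
eps_dhb <- gauss(lambda, 430, 28, 110000) +
  gauss(lambda, 556, 17, 40000) +
  15000 / (1 + exp((lambda - 613) / 16)) + 800

stopifnot(all(eps_hbo2 > 0), all(eps_dhb > 0))

ext <- data.frame(
  wavelength_nm = lambda,
  eps_HbO2 = round(eps_hbo2, 1),
  eps_dHb = round(eps_dhb, 1)
)

# Non-hemoglobin baseline absorption shape: smooth featureless power-law decay
base <- data.frame(
  wavelength_nm = lambda,
  mua_base = signif((lambda / 500)^(-3.255), 8)
)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

ext_header <- c(
  "# Synthetic hemoglobin molar extinction table (parametric approximation).",
  "# Columns: wavelength_nm, eps_HbO2, eps_dHb; units cm^-1 M^-1.",
  "# Band positions/magnitudes match published values (HbO2 542/577 nm, dHb ~556 nm);",
  "# shapes are analytic (Gaussian bands + Soret tail), NOT digitized measurements."
)
writeLines(
  c(ext_header, paste(colnames(ext), collapse = "\t"),
    apply(ext, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = "\t"))),
  "inst/extdata/hemoglobin_extinction_synthetic.tsv"
)

base_header <- c(
  "# Non-melanin baseline tissue absorption shape: (lambda/500)^-3.255, cm^-1",
  "# scaled at fit time by the dimensionless baseline parameter s_base."
)
writeLines(
  c(base_header, paste(colnames(base), collapse = "\t"),
    apply(base, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = "\t"))),
  "inst/extdata/baseline_absorption.tsv"
)

message("wrote fixtures: ", nrow(ext), " rows")
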