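# Shared fixtures: parameter pairs pulled from the packaged relaxivity
# records, and small helpers used across test files.

records <- load_relaxivity_records()
cc2 <- get_relaxivity_pair(records, "CC", 2, "Gd-DTPA")
cortex2 <- get_relaxivity_pair(records, "cortex", 2, "Gd-DTPA")

# The two preparations compared throughout: gadolinium-free 4% PFA tissue
# and the 2% PFA + 15 mM Gd-DTPA preparation implied by the CC records.
std_tissue <- tissue_relaxation(1705, 52)
opt_tissue <- tissue_relaxation(relaxation_time(cc2$t1, 15),
                                relaxation_time(cc2$t2, 15))

# Independent closed-form evaluators (deliberately separate from the
# package's .se_signal path) used as oracles.
se_full_ref <- function(t1, t2, te, tr)
  (1 - 2 * exp(-(tr - te / 2) / t1) + exp(-tr / t1)) * exp(-te / t2)
se_simple_ref <- function(t1, t2, te, tr)
  (1 - exp(-tr / t1)) * exp(-te / t2)
eff_ref <- function(t1, t2, te, tr, variant = "full") {
  s <- if (variant == "full") se_full_ref(t1, t2, te, tr)
       else se_simple_ref(t1, t2, te, tr)
  pmax(s, 0) / sqrt(tr)
}
rt_ref <- function(t0, r, ca) 1 / (1 / t0 + r * ca * 1e-3)
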