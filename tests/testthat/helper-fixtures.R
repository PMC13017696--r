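# Shared fixture builders (all in code; no stored data files).

flatSpec <- function(value, label = "flat", grid = canonicalGrid(),
                     role = "reflectance") {
  Spectrum(grid, rep(value, length(grid)), label = label, role = role)
}

gaussSpec <- function(peak, sd, amp = 1, grid = canonicalGrid(),
                      role = "sensitivity", label = "gauss") {
  Spectrum(grid, amp * exp(-(grid - peak)^2 / (2 * sd^2)),
           label = label, role = role)
}

# small dichromat viewer for closed-form checks
dichromatVS <- function(weberRef = 0.05, abundances = c(1, 1)) {
  VisualSystem(
    list(S = gaussSpec(420, 35, label = "S"),
         L = gaussSpec(560, 40, label = "L")),
    doubleCone = gaussSpec(540, 60, label = "D"),
    abundances = abundances, weberRef = weberRef, name = "dichromat")
}

# a positive random catch object with n channels
randomCatches <- function(n, label = "x") {
  new("QuantumCatches", single = exp(rnorm(n, 0, 0.5)),
      double = exp(rnorm(1, 0, 0.5)), normalized = TRUE,
      stimulusLabel = label, backgroundLabel = "bg")
}

# survival records data.frame from parallel vectors with defaults
makeRecords <- function(event_day, event, tree_id,
                        color = "green", group = "solitary",
                        transect = 1L, replacement = FALSE,
                        exposed = "exposed", entry_day = 0L) {
  n <- length(event_day)
  data.frame(individual_id = seq_len(n),
             transect = rep_len(transect, n),
             tree_id = rep_len(tree_id, n),
             treatment_color = rep_len(color, n),
             treatment_group = rep_len(group, n),
             exposed = rep_len(exposed, n),
             entry_day = rep_len(entry_day, n),
             event_day = event_day,
             event = event,
             replacement = rep_len(replacement, n),
             stringsAsFactors = FALSE)
}
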