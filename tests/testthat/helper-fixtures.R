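# Shared fixtures, all built in code.

# single constant-hazard cause for both sexes
const_hazard <- function(rate = 0.02, cap = 5000) {
  hazard_table(data.frame(cause = "X", sex = sexes(),
                          age_lo = 0, age_hi = cap, rate_per_py = rate),
               max_age = cap)
}

# two constant-hazard causes (A, B); B is residual
two_cause_hazard <- function(rA = 0.01, rB = 0.03, cap = 5000) {
  hazard_table(data.frame(cause = rep(c("A", "B"), each = 2),
                          sex = rep(sexes(), 2),
                          age_lo = 0, age_hi = cap,
                          rate_per_py = rep(c(rA, rB), each = 2)),
               max_age = cap)
}

# all-ones RR table for the given causes
unit_rr <- function(causes) {
  rr_table(expand.grid(cause = causes, sex = sexes(),
                       state = smoking_states(), rr = 1,
                       stringsAsFactors = FALSE))
}

# RR table with a given multiplier for current smokers on one cause
current_rr <- function(causes, cause, mult,
                       former = rep(1, 4)) {
  d <- expand.grid(cause = causes, sex = sexes(),
                   state = smoking_states(), rr = 1,
                   stringsAsFactors = FALSE)
  d$rr[d$cause == cause & d$state == "current"] <- mult
  for (b in 1:4)
    d$rr[d$cause == cause & d$state == smoking_states()[2 + b]] <- former[b]
  rr_table(d)
}

# the default six-cause synthetic world
synth_world <- function() {
  spec <- synthetic_spec()
  list(spec = spec, h = make_hazards(spec), rr = make_rr(spec),
       rr0 = make_rr(spec, null = TRUE), rates = smoking_rates(),
       causes = spec_causes(spec))
}

# smoking rates with all cessation hazards zero
no_cessation_rates <- function(initiation = c(female = 0.35, male = 0.39)) {
  smoking_rates(initiation = initiation,
                cessation = transform(default_cessation(), hazard = 0))
}

extdata <- function(f) system.file("extdata", f, package = "smokesim")
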