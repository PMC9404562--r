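# shared in-code fixtures

demo_western_diet <- function() {
  medium_condition(
    stats::setNames(rep(10, length(western_diet_nutrients())),
                    western_diet_nutrients()),
    aerobic = FALSE)
}

# minimal 3-reaction organism: glucose in, converted at yield 0.5, biomass out;
# analytic optimum at lb(EX_glc) = -10 is growth 5
tiny_model <- function(glc_lb = -10) {
  metabolic_model(
    id = "tiny",
    metabolites = data.frame(id = c("glc_e", "bio_c"),
                             compartment = c("e", "c")),
    reactions = data.frame(
      id = c("EX_glc_e", "R_grow", "BIOMASS"),
      lower_bound = c(glc_lb, 0, 0),
      upper_bound = c(1000, 1000, 1000),
      objective_coefficient = c(0, 0, 1)),
    stoichiometry = list(EX_glc_e = c(glc_e = -1),
                         R_grow = c(glc_e = -1, bio_c = 0.5),
                         BIOMASS = c(bio_c = -1)))
}
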