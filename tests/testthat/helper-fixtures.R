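# Small fixtures built in code.

# Nuclear family: two founders, two children (sibs).
nuclear_family <- function() {
  pedigree(
    fam = rep("f1", 4), id = c("fa", "mo", "c1", "c2"),
    father = c(NA, NA, "fa", "fa"), mother = c(NA, NA, "mo", "mo"),
    sex = c(1, 2, 1, 2)
  )
}

# Three-generation pedigree whose grandchildren are first cousins.
cousin_pedigree <- function() {
  pedigree(
    fam = rep("f1", 8),
    id = c("gf", "gm", "p1", "p2", "s1", "s2", "k1", "k2"),
    father = c(NA, NA, "gf", "gf", NA, NA, "p1", "p2"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "s1", "s2"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 1)
  )
}

small_cohort <- function(n_families = 6, template = "llfs8") {
  ped <- make_synthetic_cohort(n_families, template)
  kin <- kinship_from_pedigree(ped)
  list(ped = ped, kin = kin,
       corr = correlation_model("kinship", kinship = kin))
}
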