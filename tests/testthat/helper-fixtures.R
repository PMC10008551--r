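# Shared fixtures, all generated in code.

write_sample_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

# tiny hand-checkable sample table (note the Unicode minus in row 1)
tiny_samples_csv <- function() {
  write_sample_csv(c(
    "sample_id,site,species,age_class,d13C_coll,d15N,cn_atomic,collagen_yield,d13C_carb,d18O_carb_vpdb",
    "TC1,Tertiveri,human,adult,−19.0,9.8,3.2,4.1,-12.0,-5.0",
    "TC2,Tertiveri,human,adult,-18.5,10.2,3.8,3.0,-11.5,-4.5",
    "TC3,Montecorvino,human,adult,-20.1,10.0,3.1,,,",
    "MC1,Montecorvino,pig,adult,-21.5,6.9,3.3,2.2,-12.5,-4.0"
  ))
}

# brute-force U statistic: pairs with a_i < b_j plus half-counts for ties
brute_force_u <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) u1 <- u1 + (x < y) + 0.5 * (x == y)
  min(u1, length(a) * length(b) - u1)
}

# a small two-source problem with near-deterministic signals
toy_two_source <- function(target, target_sd = 0.1) {
  s1 <- food_source("A", protein = list(d13C = c(-26, 0.01)),
                    energy = list(d13C = c(-26, 0.01)),
                    c(protein = 0.5, energy = 0.5), 0)
  s2 <- food_source("B", protein = list(d13C = c(-11, 0.01)),
                    energy = list(d13C = c(-11, 0.01)),
                    c(protein = 0.5, energy = 0.5), 0)
  px <- mixing_proxy("d13C", "d13C", target, target_sd, 0, 0,
                     c(protein = 0.5, energy = 0.5))
  build_problem(list(s1, s2), list(px))
}

expect_monotone_loglik <- function(trace, tol = 1e-6) {
  expect_true(all(diff(trace) >= -tol * pmax(1, abs(trace[-length(trace)]))))
}
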