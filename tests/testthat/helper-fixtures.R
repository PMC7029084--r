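# shared fixtures, built in code

# small mixed-order amphibian-style table
make_toy_table <- function() {
  df <- data.frame(
    species = c("Rana alpha", "Rana beta", "Bufo gamma", "Triturus delta",
                "Salamandra eps", "Proteus zeta"),
    group = c("Anura", "Anura", "Anura", "Caudata", "Caudata", "Caudata"),
    body_mass = c(10, 40, 90, 5, 20, 35),
    clutch_size = c(800, 2000, 5000, 150, 30, 60),
    larval_period = c(60, 75, 62, 80, NA, 90),
    stringsAsFactors = FALSE)
  trait_table(df, traits = c("clutch_size", "larval_period"),
              units = c(body_mass = "g", clutch_size = "count",
                        larval_period = "days"))
}

# the canonical 3-taxon worked tree
make_worked_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
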