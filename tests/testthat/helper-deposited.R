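# Locations searched for the two deposited GenBank records (MH115428,
# MH122656), which are not redistributed with the package. Drop the flat
# files into tests/testthat/deposited/ (source tree) or
# inst/extdata/deposited/ to enable the sequence-level acceptance checks.
deposited_genbank_paths <- function() {
  accs <- c("MH115428", "MH122656")
  candidates <- c(
    testthat::test_path("deposited"),
    system.file("extdata", "deposited", package = "mitocomp")
  )
  for (dir in candidates) {
    paths <- file.path(dir, paste0(accs, ".gb"))
    if (all(file.exists(paths))) return(paths)
  }
  file.path(candidates[1L], paste0(accs, ".gb"))
}
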