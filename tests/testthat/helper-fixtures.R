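# Small in-code fixtures shared across test files.

# A five-document corpus straddling the date window and code criteria.
tiny_corpus <- function() {
  patent_corpus(
    doc_id = sprintf("D%d", 1:5),
    grant_date = as.Date(c("1994-12-31", "2000-06-01", "2005-03-15",
                           "2017-12-31", "2010-07-04")),
    title = c("Implantable cardiac device",
              "Composition for treating type 2 diabetes mellitus",
              "Network routing protocol",
              "Antibody formulation for treating influenza",
              "Diabetes mellitus monitoring system"),
    abstract = c("", "", "", "", ""),
    claims = c("", "", "", "", ""),
    uspc = list("607", character(0), "709", character(0), "600"),
    cpc = list(character(0), "A61K31/00", "H04L45/00", "A61K39/42",
               "A61B5/145")
  )
}

tiny_criteria <- function() {
  filter_criteria(date_start = "1995-01-01", date_end = "2017-12-31",
                  uspc_allowlist = c("600", "607"),
                  cpc_allowlist = c("A61K", "A61B"),
                  match_mode = "prefix")
}

# Lexicon exercising longest-match behaviour.
tiny_lexicon <- function() {
  lexicon(
    term = c("type 2 diabetes", "diabetes mellitus",
             "type 2 diabetes mellitus", "influenza"),
    cui = c("C0011860", "C0011849", "C0011860", "C0021400")
  )
}

# Bundle with a one-to-one, a many-to-one and a one-to-many rollup.
tiny_bundle <- function() {
  mapping_bundle(
    cui_to_icd9 = data.frame(
      source = c("C0011860", "C0011849", "C0011849", "C0021400", "C0021400"),
      target = c("250.00", "250.00", "250.01", "487.1", "487.8")),
    icd9_to_phecode = data.frame(
      source = c("250.00", "250.01", "487.1", "487.8"),
      target = c("250.2", "250.2", "481.0", "482.0")),
    phecode_to_root = data.frame(
      source = c("250.2", "481.0", "482.0", "250", "481", "482"),
      target = c("250", "481", "482", "250", "481", "482"))
  )
}
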