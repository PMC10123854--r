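# Small in-code fixtures shared across tests.

tiny_panel <- function() {
  data.frame(
    cas = c("7440-38-2", "7439-92-1", "67-66-3", "141-78-6"),
    name = c("arsenic", "lead", "trichloromethane", "ethyl acetate"),
    analyte_class = c("inorganic", "inorganic", "DBP", "VOC"),
    units = "ug/L",
    mdl = c(0.04, 0.04, 0.05, 0.02),
    loq = c(0.1, 0.1, 0.1, 0.05),
    reporting_limit = c(0.1, 0.1, 0.1, 0.05),
    molecular_weight = c(NA, NA, 119.38, 88.11),
    stringsAsFactors = FALSE)
}

tiny_samples <- function(n = 3) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             source_type = rep(c("purified_TW", "spring"),
                               length.out = n),
             origin = "domestic", stringsAsFactors = FALSE)
}

tiny_study <- function(conc = c(0.5, 1.1, 8, 0.06),
                       blanks = NULL, n = 3) {
  panel <- tiny_panel()
  recs <- expand.grid(sample_id = tiny_samples(n)$sample_id,
                      cas = panel$cas, stringsAsFactors = FALSE)
  recs$concentration <- rep(conc, each = n)
  bl <- if (is.null(blanks)) NULL else
    data.frame(sample_id = "BLK01", cas = names(blanks),
               concentration = unname(blanks), stringsAsFactors = FALSE)
  bw_study(tiny_samples(n), panel, recs,
           blanks = if (is.null(bl))
             data.frame(sample_id = character(), cas = character(),
                        concentration = numeric()) else bl)
}

# A study where detection patterns are stated per analyte as a list of
# sample indices; concentrations placed comfortably above the LOQ.
study_from_pattern <- function(pattern, samples = tiny_samples(3),
                               panel = default_panel()) {
  rows <- list()
  for (cas in names(pattern)) {
    ids <- samples$sample_id[pattern[[cas]]]
    if (length(ids)) {
      rows[[cas]] <- data.frame(sample_id = ids, cas = cas,
                                concentration = 1.0,
                                stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, rows)
  bw_study(samples, panel, recs)
}

small_synth_config <- function(seed) {
  synthetic_config(n_purified_tw = 3, n_spring_domestic = 4,
                   n_spring_imported = 2, seed = seed)
}
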