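# Shared fixtures, built in code at test time.

two_fold_doses <- function(Dm, n = 5L) Dm * 2^(seq_len(n) - (n + 1) / 2)

# noiseless single-agent series straight from the median-effect model
exact_dr <- function(id = "a", Dm = 10, m = 2, nRep = 1L, doses = NULL) {
  if (is.null(doses)) doses <- two_fold_doses(Dm)
  simulateDoseResponse(AgentModel(id, Dm, m), doses, nRep = nRep, cv = 0)
}

# a small valid layout data.frame for constructing PlateLayout by hand
tiny_layout_df <- function() {
  data.frame(
    row = c(1, 1, 2, 2, 1, 2),
    col = c(1, 2, 1, 2, 3, 3),
    role = c(rep("negative_control", 2), rep("positive_control", 2),
             "library", "library"),
    compound_id = c(NA, NA, NA, NA, "c1", "c2"),
    concentration = c(NA, NA, NA, NA, 10, 10),
    pt_drug_id = NA_character_, pt_concentration = NA_real_)
}

# plate with exact control signals and chosen well signals, via direct
# PlateRead construction (no noise, no simulation)
manual_plate <- function(neg = 1000, pos = 100, extra = NULL) {
  lay_df <- tiny_layout_df()
  sig <- c(neg, neg, pos, pos, if (is.null(extra)) c(500, 500) else extra)
  layout <- PlateLayout("M", lay_df)
  read <- PlateRead("M", data.frame(row = lay_df$row, col = lay_df$col,
                                    signal = sig))
  list(layout = layout, read = read)
}
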