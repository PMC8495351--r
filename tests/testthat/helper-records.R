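# Fixture builders: single records and small tables in the canonical schema.

make_record <- function(study_id = "S1", bw_kg = 640, my_kg_d = 34,
                        fat_pct = 3.5, wol = 15, parity = "multiparous",
                        ndf_pct_dm = 33.6, cp_pct_dm = 16.9,
                        adf_pct_dm = 20.5, starch_pct_dm = 24.2,
                        fpdm_pct = 51, dmi_kg_d = 22.7, breed = "Holstein",
                        ...) {
  data.frame(study_id = study_id, cow_id = NA_character_, breed = breed,
             bw_kg = bw_kg, my_kg_d = my_kg_d, fat_pct = fat_pct, wol = wol,
             parity = parity, ndf_pct_dm = ndf_pct_dm,
             cp_pct_dm = cp_pct_dm, adf_pct_dm = adf_pct_dm,
             starch_pct_dm = starch_pct_dm, fpdm_pct = fpdm_pct,
             dmi_kg_d = dmi_kg_d, ..., stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# Study-clustered table with given per-study sizes.
records_with_sizes <- function(sizes) {
  do.call(rbind, lapply(seq_along(sizes), function(i) {
    do.call(rbind, replicate(sizes[i],
                             make_record(study_id = names(sizes)[i]),
                             simplify = FALSE))
  }))
}
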