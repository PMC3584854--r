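# salsar — local active-site matching for enzyme function annotation

Most structural-genomics proteins have a solved 3D structure but an
unknown or merely putative biochemical function, and transferring the
annotation of the best global sequence or fold match is often wrong: a
single fold (TIM barrel, Rossmann) can host dozens of chemistries. `salsar`
tests function hypotheses *locally*, at the predicted catalytic site. It is
aimed at structural bioinformaticians who have, per protein, a structure
(PDB) and a per-residue functional-likelihood ranking (POOL-style), and who
want to confirm, reject, or re-assign a putative annotation.

## Method

For each structure the predicted site is the top fraction (typically
8–9%) of its residue ranking. Sites of related structures are brought into
correspondence by sequence-seeded iterative Kabsch superposition (or an
imported multiple alignment) and laid out as a table whose rows are
structures and whose columns are spatially aligned positions; cells are
residues (uppercase = predicted, lowercase = present but unpredicted) or
gaps. A functional subclass with several characterized members gets a
**consensus signature**: the positions where a strict majority of reference
rows carry a predicted residue of the same type. A query row is scored
against a signature with BLOSUM62:

    S  = Σᵢ s62(cᵢ′, qᵢ′)        cᵢ′, qᵢ′ = actual type if predicted, else X
    M  = Σᵢ s62(aᵢ, aᵢ)          perfect self-match over actual types
    %% = round(100 · S / M)      halves away from zero

with gap cells contributing a fixed penalty (default −3). High percentages
support an annotation; negative ones argue against it.

## Worked example

Six orotidine 5'-monophosphate decarboxylase (OMPDC) structures ship as a
packaged table: five previously characterized enzymes and the
structural-genomics query `2aqw`, a putative OMPDC.

```r
library(salsar)
t2  <- load_paper_fixture("omdc_table2")
sig <- derive_consensus(t2, c("1dbt", "1dvj", "1dqw", "1l2u", "2za1"))
sig
#> <consensus_signature> (D, K, D, K, D, H, P, R) from consensus; maximum self-match 48
score_table_row(t2, "1dbt", sig)
#> <match_score> raw 48 / max 48 = 100% of maximum
score_table_row(t2, "2aqw", sig)
#> <match_score> raw 39 / max 48 = 81% of maximum
```

The signature is the classic OMPDC catalytic constellation
(Asp-Lys-Asp-Lys-Asp across the barrel, plus His, Pro, Arg); a reference
row matches it perfectly (48, i.e. 100%). The query matches at 7 of 8
positions; at the eighth it has an asparagine the ranker did not predict,
scored as `X`, giving 39 = 81% of maximum — a strong local match that
supports the putative OMPDC assignment. Conversely, scoring a putative
sugar hydrolase (`3h3l`) against the 14-position glycoside-hydrolase
signature row gives a *negative* score:

```r
t3 <- load_paper_fixture("gh16_table3")
score_table_row(t3, "3h3l", row_signature(t3, "2ayh"))
#> <match_score> raw -5 / max 97 = -5% of maximum
```

— evidence that the glucanohydrolase function cannot be transferred.

## Command line

```sh
salsa simulate --n-structures 5 --n-residues 50 --seed 1 --out fam/
salsa table --structures fam/S1.pdb,...,fam/S5.pdb \
            --rankings fam/S1_rankings.tsv,...,fam/S5_rankings.tsv \
            --top-fraction 0.16 --out run/
salsa consensus --table run/salsa_table.tsv --references S1,S2,S3,S4
salsa score --table run/salsa_table.tsv --query S5 --references S1,S2,S3,S4
```

(Installed under `exec/`; equivalently `salsar::salsa_cli(c(...))`.)

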