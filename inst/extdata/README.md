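# extdata

Place the deposited 296-plant scaled reference trait table here as
`reference_traits.csv` (or point `options(rootlda.reference_table = ...)`
at it) to activate the reference-reproduction acceptance test. The file
is not redistributable with the package. Headers may use either the
package's canonical variable names or the spelled-out trait names;
`read_trait_csv()` maps both.
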