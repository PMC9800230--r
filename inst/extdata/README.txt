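Bundled plain-text fixtures.

regional_*.csv  Published regional drug-utilization figures for chronic PPI
                use in Pays de la Loire, France, 2017-2020 (incident and
                prevalent cohort demographics, yearly discontinuation counts
                with the deaths-before-October-31 tally, renewal counts by
                prescriber specialty, initiation growth, and the dispensation
                mix by INN x dosage). Used as inputs for the worked-example
                arithmetic in the tests and the acceptance script.

drug_reference.csv  Example defined-daily-dose reference values for the five
                oral PPIs (synthetic example values for the simulator, not an
                asserted transcription of the WHO ATC/DDD index).
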