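iso_field,iso_requirement,element_id,status
subject of care identifier,required,pt-04,mapped
subject of care name,required,pt-01,mapped
subject of care date of birth,required,pt-02,mapped
subject of care sex,required,pt-03,mapped
specimen type,required,sp-02,mapped
specimen collection date,required,sp-04,mapped
specimen identifier,required,sp-01,mapped
test requested,required,rq-04,mapped
indication for testing,required,rq-07,mapped
indication for testing,required,rq-08,mapped
ordering physician,required,rq-05,mapped
performing laboratory,required,ms-06,mapped
laboratory contact information,required,ms-07,mapped
test methodology,required,mt-01,mapped
sequencing platform,required,mt-02,mapped
gene(s) examined,required,rs-02,mapped
variant description,required,rs-03,mapped
variant description,required,rs-04,mapped
variant description,required,rs-05,mapped
reference sequence,required,rs-12,mapped
reference sequence,required,rs-13,mapped
variant classification,required,in-01,mapped
level of evidence,required,in-02,mapped
clinical interpretation summary,required,in-08,mapped
clinical interpretation summary,required,rs-17,mapped
recommendations,required,in-05,mapped
recommendations,required,in-06,mapped
report identifier,required,ms-01,mapped
report status,required,ms-02,mapped
report issue date,required,ms-03,mapped
order received date,required,,unmapped_iso_side
addendum creation date,required,,unmapped_iso_side
subject of care ethnicity,required,,unmapped_iso_side
medical specialty of ordering physician,required,,unmapped_iso_side
order date,optional,rq-06,mapped
performance characteristics,optional,mt-03,mapped
performance characteristics,optional,mt-04,mapped
performance characteristics,optional,mt-05,mapped
variant zygosity,optional,rs-08,mapped
variant origin,optional,rs-06,mapped
specimen body site,optional,sp-06,mapped
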