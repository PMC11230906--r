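>KE1
EKEKEKEKKEEKEKEKKEEKKKEEKEKEEKKKEEKEKEEKEKKEKEEKEK
>KE2
KKEKEEEKKKEEKEEEEKKEKEKKKKKKKEEEKKKKKEEKEEEEEKKEEE
>KE3
KKEEKKKKKKEEEKKKKEKKKEEEEKKKEKKEKEEEEKEEEKEKEEEEEK
>KE4
EEEKEKEEKEEEEKKKEEEKEEEEEEKEEEKKKKKEKKKKKEEKKKKKKK
>KE5
EEEEEEEKEEEEEKEEEKEKKKKEEEKKEKEKKKKKKEEKKEKKKKKEKK
>KE6
EEEEKEEEEEKKEEEEEEEKEKEEEKKEKKKKKKKKKKKKKKKEKEKEEK
>KE7
KKKKKKKKKKKKEKEKKKKKKEEEEEEEEKEEEEEEEKKEEEEKKEEEEK
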