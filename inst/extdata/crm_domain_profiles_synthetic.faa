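>GAG synthetic consensus profile
ETVFHQQMKRPTCKKTKDRMFLHHFCDRMFPFPHNRREDSVDRFFSFTDIKTQRGNHGMD
>PRO synthetic consensus profile
RQLKSWPLCECPQYTLDKAFTRPIHRRKLTCHMATCAVMWEVFVY
>RT synthetic consensus profile
VMRLRLPHTNQWVIWWIHMCQQGENCFQLFAFDVRWVFELAEKALEWLSGDFGLLQKYQYYKNGFNLKDL
>RH synthetic consensus profile
VLRDWWIDIQFRLASQERGAGDYAAIAFQSPPQDDCHWKVSYDNDSWGRLAHPYT
>INT synthetic consensus profile
TSGLLRKNDPLENAQTSGEQSNPRQRARWCMIQADYWNEHAMKFFEDFVLHQANMPPLHGWEYQT
>CHD synthetic consensus profile
MFDAQSNVIPPINITWNQRAREYHDGLAGKVIEGVVQCGLNFPLHYDLVE
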